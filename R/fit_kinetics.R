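# Kinetic-model fitting to scaled enrichment data.
#
# Free parameters for n subpopulations: n log turnover rates and n-1
# stick-breaking logits for the fractions (2n-1 in total). The product
# c*f is fixed to 1 because the data have been scaled by the granulocyte
# asymptote, which absorbs both the amplification factor and the plasma
# plateau.

theta_split <- function(theta, n) {
  list(p = exp(theta[seq_len(n)]),
       alpha = alpha_from_stick(theta[n + seq_len(max(n - 1, 0))]))
}

theta_build <- function(p, alpha) {
  c(log(pmax(p, 1e-12)), stick_from_alpha(alpha))
}

# Unit-plateau mixture prediction (c*f = 1) at times t.
scaled_prediction <- function(t, p, alpha, bw) {
  out <- numeric(length(t))
  for (i in seq_along(p))
    out <- out + alpha[i] * unit_enrichment(t, p[i], bw$delta, bw$tau)
  out
}

# Starts for n+1 subpopulations nested in an n-subpopulation solution:
# (i) duplicate the fastest subpopulation with its fraction split (the
# prediction, hence the objective, is unchanged exactly), and (ii/iii) a
# fast and a slow probe entering with a near-zero fraction.
nested_starts <- function(pops) {
  starts <- list(theta_build(c(pops$p, pops$p[1]),
                             c(pops$alpha[1] / 2, pops$alpha[-1],
                               pops$alpha[1] / 2)))
  for (p_new in c(0.5, 1e-3)) {
    starts[[length(starts) + 1]] <- theta_build(
      c(pops$p, p_new), c(pops$alpha * (1 - 1e-4), 1e-4))
  }
  starts
}

kinetic_objective <- function(theta, n, t_obs, z_obs, bw) {
  pa <- theta_split(theta, n)
  if (any(!is.finite(pa$p)) || any(pa$p > 50)) return(Inf)
  pred <- scaled_prediction(t_obs, pa$p, pa$alpha, bw)
  sum((z_obs - asin(sqrt(clamp01(pred))))^2)
}

# Multi-start minimization; extra_starts are parameter vectors prepended to
# the quasi-random Latin-hypercube starts (used for warm/nested starts).
minimize_kinetic <- function(n, t_obs, z_obs, bw, starts, seed,
                             extra_starts = list(), polish = 3) {
  k <- 2 * n - 1
  obj <- function(th) kinetic_objective(th, n, t_obs, z_obs, bw)
  if (n == 1) {
    opt <- stats::optimize(function(lp) obj(lp), log(c(1e-6, 10)),
                           tol = 1e-12)
    best <- list(par = opt$minimum, value = opt$objective, converged = TRUE)
    for (th0 in extra_starts) {
      opt2 <- stats::optimize(function(lp) obj(lp),
                              c(th0 - 2, th0 + 2), tol = 1e-12)
      if (opt2$objective < best$value)
        best <- list(par = opt2$minimum, value = opt2$objective,
                     converged = TRUE)
    }
    return(best)
  }
  start_list <- extra_starts
  if (starts > 0) {
    grid <- with_seed(child_seed(seed, 29 + n), lhs::randomLHS(starts, k))
    for (i in seq_len(starts)) {
      p0 <- exp(log(1e-4) + grid[i, seq_len(n)] * (log(1) - log(1e-4)))
      a0 <- if (n > 1) simplex_from_uniform(grid[i, n + seq_len(n - 1)]) else 1
      start_list[[length(start_list) + 1]] <- theta_build(p0, a0)
    }
  }
  results <- list()
  for (th0 in start_list) {
    fit <- tryCatch(
      stats::optim(th0, obj, method = "Nelder-Mead",
                   control = list(maxit = 3000, reltol = 1e-13)),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value))
      results[[length(results) + 1]] <- fit
  }
  if (length(results) == 0)
    stop("kinetic-model fit failed to converge in all starts")
  ord <- order(vapply(results, `[[`, numeric(1), "value"))
  best <- results[[ord[1]]]
  for (j in utils::head(ord, polish)) {
    pol <- tryCatch(
      stats::optim(results[[j]]$par, obj, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(pol) && is.finite(pol$value) && pol$value < best$value)
      best <- pol
  }
  best$converged <- TRUE
  best
}

#' Fit a kinetic mixture model to scaled enrichment data
#'
#' Minimizes the residual sum of squares, on the arcsine-square-root
#' scale, between scaled DNA enrichment observations and the mixture
#' enrichment curve with `n_subpops` kinetically distinct subpopulations.
#' The product of amplification factor and plasma plateau is fixed to 1
#' (the data must already be scaled by the granulocyte asymptote, see
#' [scale_enrichment()]). Fractions are parameterized by stick-breaking on
#' a logistic scale and rates on a log scale, so the simplex and
#' positivity constraints hold by construction; the likelihood surface of
#' exponential mixtures is multimodal, so quasi-random multi-start local
#' optimization is used. A redundant subpopulation may collapse
#' (`alpha` near 0 or coinciding rates), which is the expected outcome when
#' `n_subpops` exceeds the true kinetic complexity.
#'
#' @param obs scaled observation data frame (all rows are fitted; filter
#'   to one compartment/subset first). Must have `scaled = TRUE`.
#' @param n_subpops number of kinetic subpopulations (>= 1).
#' @param bw fitted [body_water_params()].
#' @param starts number of quasi-random initializations (default 25).
#' @param seed integer seed controlling the start sequence.
#' @param extra_starts optional list of parameter vectors to use as
#'   additional starts (internal use: warm and nested starts).
#' @return An object of class `kinetic_fit`: the canonical-ordered
#'   [kinetic_model()] (with `c` set to `1/f` so that `c*f = 1`), `rss`,
#'   transformed-scale `residuals` aligned to `obs`, `fitted_transformed`,
#'   `avg_turnover` (per day), `lifespan` (days), and bootstrap slots
#'   (`ci`, `boot`, `n_boot`) filled by [bootstrap_confidence()].
#' @seealso [select_n_subpopulations()], [bootstrap_confidence()]
#' @export
fit_kinetic_model <- function(obs, n_subpops, bw, starts = 25, seed = 1,
                              extra_starts = list()) {
  validate_observations(obs, "scaled observations")
  stopifnot(inherits(bw, "body_water_params"), n_subpops >= 1)
  if (!all(obs$scaled))
    stop("observations must be scaled by the granulocyte asymptote first")
  k <- 2 * n_subpops - 1
  if (nrow(obs) < k + 1)
    stop("under-identified: ", nrow(obs), " observations for ", k,
         " free parameters")
  t_obs <- obs$time_days
  z_obs <- as.numeric(variance_stabilize(obs$value))
  if (n_subpops > 1 && length(extra_starts) == 0) {
    # nested starts from the (n-1)-subpopulation fit guarantee that the
    # residual sum of squares is non-increasing in n_subpops
    base <- fit_kinetic_model(obs, n_subpops - 1, bw, starts = starts,
                              seed = seed)
    extra_starts <- nested_starts(base$model$populations)
  }
  best <- minimize_kinetic(n_subpops, t_obs, z_obs, bw, starts, seed,
                           extra_starts = extra_starts)
  pa <- theta_split(best$par, n_subpops)
  model <- kinetic_model(alpha = pa$alpha, p = pa$p, c = 1 / bw$f)
  pred <- asin(sqrt(clamp01(
    scaled_prediction(t_obs, pa$p, pa$alpha, bw))))
  pbar <- average_turnover(model)
  structure(list(
    model = model, n_subpops = n_subpops, rss = best$value,
    residuals = z_obs - pred, fitted_transformed = pred,
    observations = obs, bw = bw,
    avg_turnover = pbar,
    lifespan = if (pbar > 0) 1 / pbar else Inf,
    ci = NULL, boot = NULL, n_boot = 0L,
    seed = seed, starts = starts, converged = isTRUE(best$converged)
  ), class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("Kinetic fit: n = %d subpopulation%s, RSS = %.5g (%d obs)\n",
              x$n_subpops, if (x$n_subpops == 1) "" else "s", x$rss,
              nrow(x$observations)))
  print(x$model)
  if (!is.null(x$ci)) {
    cat(sprintf("  95%% CI lifespan: [%.4g, %.4g] d (%d bootstrap replicates)\n",
                x$ci$lifespan[1], x$ci$lifespan[2], x$n_boot))
  }
  invisible(x)
}

#' Stepwise selection of the number of kinetic subpopulations
#'
#' Fits models with increasing numbers of kinetically distinct
#' subpopulations, adding one at a time until the fit no longer improves
#' significantly *and* meaningfully: the extra subpopulation is accepted
#' when the nested-model F-test (2 extra parameters) is significant at
#' `alpha` and the average turnover rate changes by more than
#' `min_rel_change` relative to the simpler model. Each candidate with
#' `n + 1` subpopulations includes a nested start built from the accepted
#' `n`-subpopulation fit (the extra subpopulation entering with a near-zero
#' fraction), which guarantees that the residual sum of squares is
#' non-increasing in `n`.
#'
#' @inheritParams fit_kinetic_model
#' @param max_n largest number of subpopulations to consider (default 3).
#' @param alpha significance level of the nested F-test.
#' @param min_rel_change minimum relative change in average turnover for an
#'   extra subpopulation to be considered meaningful.
#' @return A list of class `subpop_selection` with elements `fit` (the
#'   accepted [fit_kinetic_model()] result) and `trace` (a data frame with
#'   one row per candidate `n`: `rss`, `avg_turnover`, `f_statistic`,
#'   `p_value`, `rel_change`, `accepted`).
#' @export
select_n_subpopulations <- function(obs, bw, max_n = 3, starts = 25,
                                    seed = 1, alpha = 0.05,
                                    min_rel_change = 0.05) {
  stopifnot(max_n >= 1)
  fits <- list()
  trace <- data.frame(n = integer(), rss = numeric(),
                      avg_turnover = numeric(), f_statistic = numeric(),
                      p_value = numeric(), rel_change = numeric(),
                      accepted = logical())
  accepted <- NULL
  n_obs <- nrow(obs)
  for (n in seq_len(max_n)) {
    extra <- if (n > 1) nested_starts(accepted$model$populations) else list()
    if (n_obs < 2 * n) break  # cannot identify more parameters
    fit_n <- fit_kinetic_model(obs, n, bw, starts = starts,
                               seed = child_seed(seed, 100 + n),
                               extra_starts = extra)
    if (n == 1) {
      trace <- rbind(trace, data.frame(
        n = 1L, rss = fit_n$rss, avg_turnover = fit_n$avg_turnover,
        f_statistic = NA_real_, p_value = NA_real_,
        rel_change = NA_real_, accepted = TRUE))
      accepted <- fit_n
      next
    }
    rss0 <- accepted$rss
    rss1 <- min(fit_n$rss, rss0)  # nested start makes this redundant in theory
    df2 <- n_obs - (2 * n - 1)
    f_stat <- if (rss1 > 0 && df2 > 0) ((rss0 - rss1) / 2) / (rss1 / df2)
              else Inf
    p_val <- if (df2 > 0) stats::pf(f_stat, 2, df2, lower.tail = FALSE)
             else NA_real_
    rel_change <- abs(fit_n$avg_turnover - accepted$avg_turnover) /
      max(accepted$avg_turnover, .Machine$double.eps)
    ok <- is.finite(f_stat) && !is.na(p_val) && p_val < alpha &&
      rel_change > min_rel_change
    trace <- rbind(trace, data.frame(
      n = as.integer(n), rss = fit_n$rss, avg_turnover = fit_n$avg_turnover,
      f_statistic = f_stat, p_value = p_val, rel_change = rel_change,
      accepted = ok))
    if (!ok) break
    accepted <- fit_n
  }
  structure(list(fit = accepted, trace = trace), class = "subpop_selection")
}

#' @export
print.subpop_selection <- function(x, ...) {
  cat("Stepwise subpopulation selection\n")
  print(x$trace, row.names = FALSE, digits = 4)
  cat(sprintf("Accepted: n = %d\n", x$fit$n_subpops))
  invisible(x)
}
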