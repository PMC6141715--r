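#' Estimate the maximum attainable enrichment from granulocytes
#'
#' Granulocytes turn over fast enough that their DNA enrichment reaches
#' the maximum level of label incorporation that any cell could attain.
#' A single kinetically homogeneous population with a free amplitude is
#' fitted to the raw granulocyte up-/down-labeling data (on the
#' arcsine-square-root scale): `L_g(t) = asymptote * u(t - delay; p_g)`,
#' where `u` is the unit-plateau enrichment curve. The fitted amplitude is
#' the granulocyte asymptote (the product of the amplification factor and
#' the plasma plateau) used by [scale_enrichment()] to normalize all cell
#' subsets. An optional maturation delay (granulocytes are released from
#' the marrow some days after the DNA-synthesizing division) can be
#' co-estimated; it is off by default.
#'
#' @param obs observation data frame whose `subset == "granulocyte"` rows
#'   are used; at least 4 observations spanning up- (t <= tau) and
#'   down-labeling (t > tau) are required.
#' @param bw fitted [body_water_params()].
#' @param allow_delay estimate a maturation delay (days, >= 0)? Default
#'   `FALSE` (delay fixed at 0).
#' @param starts number of multi-start initializations.
#' @param seed integer seed for the start sequence.
#' @return A list of class `granulocyte_fit`: `asymptote`, `p_g` (per
#'   day), `delay` (days), `rss` (transformed scale), `residuals`,
#'   `n_obs`, and `degenerate` (TRUE when the data carry no label signal).
#' @export
fit_granulocyte_asymptote <- function(obs, bw, allow_delay = FALSE,
                                      starts = 16, seed = 1) {
  validate_observations(obs, "granulocyte observations")
  stopifnot(inherits(bw, "body_water_params"))
  gr <- obs[obs$subset == "granulocyte", , drop = FALSE]
  if (nrow(gr) < 4)
    stop("under-identified: need at least 4 granulocyte observations, got ",
         nrow(gr))
  if (!any(gr$time_days <= bw$tau) || !any(gr$time_days > bw$tau))
    stop("under-identified: granulocyte observations must span up- and ",
         "down-labeling")
  if (any(gr$scaled))
    stop("granulocyte observations must be raw (unscaled)")
  t_obs <- gr$time_days
  z_obs <- as.numeric(variance_stabilize(gr$value))
  degenerate <- all(gr$value == 0)
  if (degenerate) {
    warning("granulocyte data are identically zero; asymptote is degenerate")
    return(structure(list(asymptote = 0, p_g = NA_real_, delay = 0,
                          rss = 0, residuals = rep(0, nrow(gr)),
                          n_obs = nrow(gr), degenerate = TRUE),
                     class = "granulocyte_fit"))
  }

  # theta = (log asymptote, log p_g[, sqrt delay])
  k <- if (allow_delay) 3L else 2L
  obj <- function(th) {
    asym <- exp(th[1]); pg <- exp(th[2])
    if (!is.finite(asym) || !is.finite(pg) || asym > 1 || pg > 50)
      return(Inf)
    delay <- if (allow_delay) th[3]^2 else 0
    tt <- pmax(t_obs - delay, 0)
    pred <- asym * unit_enrichment(tt, pg, bw$delta, bw$tau)
    sum((z_obs - asin(sqrt(clamp01(pred))))^2)
  }
  grid <- with_seed(child_seed(seed, 37), lhs::randomLHS(starts, k))
  ths <- cbind(log(0.005) + grid[, 1] * (log(0.5) - log(0.005)),
               log(0.02) + grid[, 2] * (log(2) - log(0.02)))
  if (allow_delay) ths <- cbind(ths, grid[, 3] * 2)
  # a start at the empirical plateau with a fast rate
  emp <- c(log(max(max(gr$value), 1e-4)), log(0.3), if (allow_delay) 0)
  ths <- rbind(ths, emp)
  best <- NULL
  for (i in seq_len(nrow(ths))) {
    fit <- tryCatch(
      stats::optim(ths[i, ], obj, method = "Nelder-Mead",
                   control = list(maxit = 3000, reltol = 1e-13)),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("granulocyte fit failed to converge in any start")
  pol <- tryCatch(
    stats::optim(best$par, obj, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-14)),
    error = function(e) NULL)
  if (!is.null(pol) && is.finite(pol$value) && pol$value < best$value)
    best <- pol
  asym <- exp(best$par[1]); pg <- exp(best$par[2])
  delay <- if (allow_delay) best$par[3]^2 else 0
  pred <- asin(sqrt(clamp01(
    asym * unit_enrichment(pmax(t_obs - delay, 0), pg, bw$delta, bw$tau))))
  structure(list(asymptote = asym, p_g = pg, delay = delay,
                 rss = best$value, residuals = z_obs - pred,
                 n_obs = nrow(gr), degenerate = asym < 1e-6),
            class = "granulocyte_fit")
}

#' @export
print.granulocyte_fit <- function(x, ...) {
  cat(sprintf(
    "Granulocyte fit (%d obs): asymptote %.5g, p_g %.4g /day, delay %.3g d, RSS %.4g%s\n",
    x$n_obs, x$asymptote, x$p_g, x$delay, x$rss,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Scale enrichment observations by the granulocyte asymptote
#'
#' Divides raw enrichment values by the fitted granulocyte asymptote —
#' the maximum attainable level of label incorporation — so that a fully
#' turned-over population plateaus at 1 and downstream kinetic fits can
#' fix the product of amplification factor and plasma plateau to 1.
#' Scaling is the only mutation; the `scaled` flag is set.
#'
#' @param obs observation data frame with `scaled = FALSE` rows.
#' @param g a [fit_granulocyte_asymptote()] result (or any list with a
#'   positive `asymptote` element).
#' @return The observation data frame with `value` divided by the
#'   asymptote and `scaled = TRUE`.
#' @export
scale_enrichment <- function(obs, g) {
  validate_observations(obs)
  if (is.null(g$asymptote) || !is.finite(g$asymptote) || g$asymptote <= 0)
    stop("granulocyte asymptote must be positive; refusing to scale",
         if (isTRUE(g$degenerate)) " (degenerate granulocyte fit)" else "")
  if (any(obs$scaled))
    stop("refusing to scale: ", sum(obs$scaled),
         " observation(s) already scaled")
  obs$value <- obs$value / g$asymptote
  obs$scaled <- TRUE
  obs
}
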