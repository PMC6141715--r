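#' Body-water enrichment curve parameters
#'
#' Parameters of the plasma heavy-water enrichment/decay curve
#' \eqn{S(t)}: during label intake (\eqn{t \le \tau}),
#' \eqn{S(t) = f(1 - e^{-\delta t})}; after intake stops the value reached at
#' \eqn{\tau} decays exponentially, \eqn{S(t) = f(1 - e^{-\delta\tau})
#' e^{-\delta(t-\tau)}}.
#'
#' @param f plateau fraction of heavy water available to cells
#'   (dimensionless, in (0, 1]). Nominally the fraction of heavy water in
#'   the drinking water, but the fitted plasma plateau may undershoot it.
#' @param delta body-water turnover rate, per day (> 0).
#' @param tau label cessation time in days (> 0); an experimental constant,
#'   never fitted.
#'
#' @return An object of class `body_water_params`.
#' @seealso [body_water_enrichment()], [fit_body_water()]
#' @export
#' @examples
#' bw <- body_water_params(f = 0.04, delta = 0.1, tau = 28)
#' body_water_enrichment(c(0, 14, 28, 56), bw)
body_water_params <- function(f, delta, tau) {
  stopifnot(is.numeric(f), length(f) == 1, is.finite(f),
            is.numeric(delta), length(delta) == 1, is.finite(delta),
            is.numeric(tau), length(tau) == 1, is.finite(tau))
  if (f <= 0 || f > 1) stop("'f' must lie in (0, 1], got ", f)
  if (delta <= 0) stop("'delta' must be > 0, got ", delta)
  if (tau <= 0) stop("'tau' must be > 0, got ", tau)
  structure(list(f = f, delta = delta, tau = tau),
            class = "body_water_params")
}

#' @export
print.body_water_params <- function(x, ...) {
  cat("Body-water enrichment parameters\n")
  cat(sprintf("  plateau fraction f: %.5g\n", x$f))
  cat(sprintf("  turnover rate delta: %.5g /day (half-life %.3g d)\n",
              x$delta, log(2) / x$delta))
  cat(sprintf("  label cessation tau: %g d\n", x$tau))
  invisible(x)
}

#' Kinetic mixture model of a cell population
#'
#' A cell population is modeled as a mixture of kinetically homogeneous
#' subpopulations: a fraction `alpha[i]` of cells turning over at rate
#' `p[i]` per day, under steady state (production = loss). The amplification
#' factor `c` accounts for the multiple hydrogen positions of the adenosine
#' deoxyribose moiety that can carry deuterium; for data already scaled by
#' the granulocyte asymptote the product `c * f` is fixed to 1.
#'
#' The model is stored in canonical form: subpopulations sorted by
#' descending turnover rate (ties broken by descending fraction), which
#' resolves label-switching ambiguity when comparing fits.
#'
#' @param alpha numeric vector of subpopulation fractions; must sum to 1
#'   (within 1e-12) with every element in \[0, 1\].
#' @param p numeric vector of subpopulation turnover rates (per day,
#'   >= 0), same length as `alpha`.
#' @param c amplification factor (> 0).
#'
#' @return An object of class `kinetic_model` with elements `populations`
#'   (data frame with columns `alpha`, `p`, canonically ordered) and `c`.
#' @seealso [average_turnover()], [mean_lifespan()], [mixture_enrichment()]
#' @export
#' @examples
#' m <- kinetic_model(alpha = c(0.7, 0.3), p = c(0.05, 0.01))
#' average_turnover(m)  # 0.038 /day
#' mean_lifespan(m)     # ~26.3 days
kinetic_model <- function(alpha, p, c = 1) {
  stopifnot(is.numeric(alpha), is.numeric(p), length(alpha) == length(p),
            length(alpha) >= 1, all(is.finite(alpha)), all(is.finite(p)),
            is.numeric(c), length(c) == 1, is.finite(c))
  if (any(alpha < 0 | alpha > 1))
    stop("subpopulation fractions 'alpha' must lie in [0, 1]")
  if (abs(sum(alpha) - 1) > 1e-12)
    stop("subpopulation fractions must sum to 1 (got ",
         format(sum(alpha), digits = 15), ")")
  if (any(p < 0)) stop("turnover rates 'p' must be >= 0")
  if (c <= 0) stop("amplification factor 'c' must be > 0")
  ord <- order(-p, -alpha)
  structure(
    list(populations = data.frame(alpha = alpha[ord], p = p[ord]), c = c),
    class = "kinetic_model"
  )
}

#' @export
print.kinetic_model <- function(x, ...) {
  k <- nrow(x$populations)
  cat(sprintf("Kinetic model: %d subpopulation%s, amplification c = %.5g\n",
              k, if (k == 1) "" else "s", x$c))
  for (i in seq_len(k)) {
    cat(sprintf("  alpha = %.4f, p = %.5g /day (lifespan %.4g d)\n",
                x$populations$alpha[i], x$populations$p[i],
                if (x$populations$p[i] > 0) 1 / x$populations$p[i] else Inf))
  }
  pbar <- average_turnover(x)
  cat(sprintf("  average turnover %.5g /day", pbar))
  if (pbar > 0) cat(sprintf(", expected lifespan %.4g d", 1 / pbar))
  cat("\n")
  invisible(x)
}

#' Average turnover rate of a kinetic mixture
#'
#' The population-average turnover rate \eqn{p = \sum_i \alpha_i p_i},
#' in per day.
#'
#' @param model a [kinetic_model()].
#' @return Average turnover rate (per day).
#' @export
average_turnover <- function(model) {
  stopifnot(inherits(model, "kinetic_model"))
  sum(model$populations$alpha * model$populations$p)
}

#' Expected lifespan of a kinetic mixture
#'
#' The expected (average) lifespan \eqn{1/p} in days, where \eqn{p} is the
#' average turnover rate.
#'
#' @param model a [kinetic_model()].
#' @return Expected lifespan in days.
#' @export
mean_lifespan <- function(model) {
  pbar <- average_turnover(model)
  if (pbar <= 0)
    stop("lifespan is undefined for a model with zero average turnover")
  1 / pbar
}

# Validate an observation data frame (the common currency of the pipeline).
# Returns the data frame invisibly; stops with row-numbered messages.
validate_observations <- function(obs, what = "observations") {
  required <- c("subject_id", "time_days", "compartment", "subset",
                "value", "scaled")
  missing_cols <- setdiff(required, names(obs))
  if (length(missing_cols) > 0)
    stop(what, ": missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(obs) == 0) stop(what, ": no rows")
  bad <- which(!is.finite(obs$time_days) | obs$time_days < 0)
  if (length(bad) > 0)
    stop(what, ": non-finite or negative time_days at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!is.finite(obs$value) | obs$value < 0)
  if (length(bad) > 0)
    stop(what, ": non-finite or negative value at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!obs$compartment %in% c("blood", "bm", "ln", "none"))
  if (length(bad) > 0)
    stop(what, ": unknown compartment at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (allowed: blood, bm, ln, none)")
  bad <- which(!obs$subset %in% c("cd4_memory", "cd8_memory", "cd4_naive",
                                  "cd8_naive", "granulocyte", "plasma"))
  if (length(bad) > 0)
    stop(what, ": unknown subset at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (!is.logical(obs$scaled) || anyNA(obs$scaled))
    stop(what, ": 'scaled' must be logical with no missing values")
  invisible(obs)
}
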