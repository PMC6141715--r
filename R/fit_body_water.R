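#' Fit the plasma body-water enrichment curve
#'
#' Least-squares fit of the enrichment/decay curve [body_water_enrichment()]
#' to plasma heavy-water measurements, on the arcsine-square-root scale.
#' The cessation time `tau` is fixed at the protocol value; the plateau `f`
#' and body-water turnover `delta` are estimated (or only `delta`, if `f`
#' is fixed at the nominal drinking-water fraction via `fix_f`).
#'
#' @param obs observation data frame (see [read_observations()]) whose rows
#'   with `subset == "plasma"` are used; at least 4 plasma observations are
#'   required, including at least one during up-labeling and one after
#'   `tau`.
#' @param tau label cessation time in days (experimental constant).
#' @param fix_f optional fraction; when given, `f` is fixed at this value
#'   and only `delta` is estimated.
#' @param starts number of multi-start initializations when both
#'   parameters are free.
#' @param seed integer seed for the start sequence.
#' @return A list of class `body_water_fit` with elements `bw`
#'   (a [body_water_params()]), `rss` (transformed scale), `residuals`,
#'   `fitted_transformed`, `n_obs`, and `fixed_f`.
#' @export
fit_body_water <- function(obs, tau, fix_f = NULL, starts = 9, seed = 1) {
  validate_observations(obs, "plasma observations")
  pl <- obs[obs$subset == "plasma", , drop = FALSE]
  if (nrow(pl) < 4)
    stop("under-identified: need at least 4 plasma observations, got ",
         nrow(pl))
  if (!any(pl$time_days <= tau) || !any(pl$time_days > tau))
    stop("under-identified: plasma observations must span up-labeling ",
         "(t <= tau) and down-labeling (t > tau)")
  if (all(pl$value == 0))
    stop("degenerate fit: all plasma values are zero")
  t_obs <- pl$time_days
  z_obs <- as.numeric(variance_stabilize(pl$value))

  obj_free <- function(th) {
    bw <- body_water_params(stats::plogis(th[1]), exp(th[2]), tau)
    pred <- body_water_enrichment(t_obs, bw)
    sum((z_obs - asin(sqrt(clamp01(pred))))^2)
  }

  if (!is.null(fix_f)) {
    stopifnot(is.numeric(fix_f), fix_f > 0, fix_f <= 1)
    obj_delta <- function(ld) {
      bw <- body_water_params(fix_f, exp(ld), tau)
      sum((z_obs - asin(sqrt(clamp01(body_water_enrichment(t_obs, bw)))))^2)
    }
    opt <- stats::optimize(obj_delta, interval = log(c(1e-4, 10)),
                           tol = 1e-12)
    bw_hat <- body_water_params(fix_f, exp(opt$minimum), tau)
    rss <- opt$objective
  } else {
    # multi-start over (logit f, log delta); plateau seeded around the
    # nominal drinking-water fraction
    grid <- with_seed(child_seed(seed, 11), lhs::randomLHS(starts, 2))
    ths <- cbind(stats::qlogis(0.005 + grid[, 1] * (0.25 - 0.005)),
                 log(0.01) + grid[, 2] * (log(1) - log(0.01)))
    ths <- rbind(ths, c(stats::qlogis(0.04), log(0.1)))
    best <- NULL
    for (i in seq_len(nrow(ths))) {
      fit <- tryCatch(
        stats::optim(ths[i, ], obj_free, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-14)),
        error = function(e) NULL)
      if (!is.null(fit) && is.finite(fit$value) &&
          (is.null(best) || fit$value < best$value)) best <- fit
    }
    if (is.null(best)) stop("body-water fit failed to converge in any start")
    pol <- tryCatch(
      stats::optim(best$par, obj_free, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(pol) && is.finite(pol$value) && pol$value <= best$value)
      best <- pol
    bw_hat <- body_water_params(stats::plogis(best$par[1]),
                                exp(best$par[2]), tau)
    rss <- best$value
  }
  pred <- asin(sqrt(clamp01(body_water_enrichment(t_obs, bw_hat))))
  structure(list(bw = bw_hat, rss = rss, residuals = z_obs - pred,
                 fitted_transformed = pred, n_obs = nrow(pl),
                 fixed_f = !is.null(fix_f)),
            class = "body_water_fit")
}

#' @export
print.body_water_fit <- function(x, ...) {
  cat(sprintf("Body-water fit (%d plasma observations, RSS %.4g%s)\n",
              x$n_obs, x$rss, if (x$fixed_f) ", f fixed" else ""))
  print(x$bw)
  invisible(x)
}
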