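#' Plasma body-water enrichment S(t)
#'
#' Fraction of heavy water in plasma at time `t` days after the start of
#' label administration. During intake the curve saturates towards the
#' plateau `f`; after the cessation time `tau` the value reached at `tau`
#' decays exponentially at the body-water turnover rate, so the curve is
#' continuous at `tau`.
#'
#' @param t time in days since the first heavy-water intake (vectorized,
#'   all values >= 0).
#' @param bw a [body_water_params()] object.
#' @return Numeric vector of enrichment fractions, `0 <= S(t) <= f`.
#' @export
body_water_enrichment <- function(t, bw) {
  stopifnot(inherits(bw, "body_water_params"), is.numeric(t))
  if (any(!is.finite(t)) || any(t < 0))
    stop("time must be finite and >= 0")
  up <- t <= bw$tau
  s <- numeric(length(t))
  s[up] <- bw$f * (1 - exp(-bw$delta * t[up]))
  s[!up] <- bw$f * (1 - exp(-bw$delta * bw$tau)) *
    exp(-bw$delta * (t[!up] - bw$tau))
  s
}

# Unit-amplitude label enrichment curve: the closed-form solution of
# dL/dt = p S(t)/f - p L with L(0) = 0, i.e. the enrichment curve with the
# product c*f scaled out (plateau 1 for p -> Inf, delta -> Inf).
#
# The generic expressions have a removable singularity at p = delta
# (a factor 1/(delta - p)); within a band around it a first-order series
# in eps = delta - p is used, which avoids catastrophic cancellation and
# keeps the curve smooth across the switch (truncation error O(eps^2),
# ~1e-12 at the band edge).
unit_enrichment <- function(t, p, delta, tau) {
  if (p == 0) return(numeric(length(t)))
  up <- t <= tau
  u <- numeric(length(t))
  if (abs(delta - p) < 1e-5 * delta) {
    eps <- delta - p
    tu <- t[up]
    u[up] <- 1 - (1 + p * tu) * exp(-p * tu) +
      eps * (p * tu^2 / 2) * exp(-p * tu)
    td <- t[!up]
    e1 <- exp(-p * (td - tau)); e2 <- exp(-p * td)
    u[!up] <- (1 + p * (td - tau)) * e1 - (1 + p * td) * e2 -
      eps * (p / 2) * ((td - tau)^2 * e1 - td^2 * e2)
  } else {
    d <- delta - p
    u[up] <- (delta * (1 - exp(-p * t[up])) -
                p * (1 - exp(-delta * t[up]))) / d
    td <- t[!up]
    u[!up] <- (delta * (exp(-p * (td - tau)) - exp(-p * td)) -
                 p * (exp(-delta * (td - tau)) - exp(-delta * td))) / d
  }
  # guard against floating fuzz at the boundaries
  pmin(pmax(u, 0), 1)
}

#' Closed-form DNA label enrichment of a homogeneous population
#'
#' Analytical solution for the fraction of labeled adenosine deoxyribose
#' in the DNA of a kinetically homogeneous population turning over at rate
#' `p` under steady state, forced by the plasma curve
#' [body_water_enrichment()]. During intake (\eqn{t \le \tau}):
#' \deqn{L(t) = \frac{cf}{\delta - p}\left[\delta(1 - e^{-pt}) -
#'   p(1 - e^{-\delta t})\right]}
#' and after intake the same expression with each saturating term replaced
#' by its decaying counterpart, so that \eqn{L} is continuous at
#' \eqn{\tau}. At \eqn{p = \delta} the singularity is removable; near it
#' the expressions are evaluated by a series expansion in
#' \eqn{\delta - p} to avoid catastrophic cancellation.
#'
#' @param t time in days (vectorized, >= 0).
#' @param p turnover rate of the population, per day (scalar, >= 0).
#' @param c amplification factor (> 0).
#' @param bw a [body_water_params()] object.
#' @return Numeric vector of enrichment fractions, `0 <= L(t) <= c*f`.
#' @seealso [enrichment_ode_rhs()] for the differential form,
#'   [mixture_enrichment()] for kinetically heterogeneous populations.
#' @export
enrichment_closed_form <- function(t, p, c, bw) {
  stopifnot(inherits(bw, "body_water_params"),
            is.numeric(p), length(p) == 1, is.finite(p),
            is.numeric(c), length(c) == 1, c > 0)
  if (p < 0) stop("turnover rate 'p' must be >= 0")
  if (any(!is.finite(t)) || any(t < 0))
    stop("time must be finite and >= 0")
  c * bw$f * unit_enrichment(t, p, bw$delta, bw$tau)
}

#' Right-hand side of the label enrichment ODE
#'
#' The differential form of label incorporation under steady state:
#' \eqn{dL/dt = p\,c\,S(t) - p\,L}. Labeled adenosine is gained when cells
#' divide at rate `p` while deuterium is available at level `c S(t)`, and
#' lost when cells die at the same rate. This is the brute-force
#' counterpart of [enrichment_closed_form()]; integrating it numerically
#' (see [enrichment_ode()]) provides an independent check of the closed
#' form.
#'
#' @param t time in days.
#' @param L current enrichment fraction.
#' @inheritParams enrichment_closed_form
#' @return dL/dt in per day.
#' @export
enrichment_ode_rhs <- function(t, L, p, c, bw) {
  p * c * body_water_enrichment(t, bw) - p * L
}

#' Numerically integrated label enrichment (oracle)
#'
#' Integrates [enrichment_ode_rhs()] from 0 with `deSolve::lsoda`,
#' piecewise over the intake and de-labeling phases so the kink in
#' \eqn{S(t)} at \eqn{\tau} does not degrade accuracy. Intended as an
#' independent numerical oracle for [enrichment_closed_form()].
#'
#' @inheritParams enrichment_closed_form
#' @param t times at which to return the solution (days, sorted or not).
#' @param rtol,atol integration tolerances passed to `lsoda`.
#' @return Numeric vector of enrichment fractions at `t`.
#' @export
enrichment_ode <- function(t, p, c, bw, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(bw, "body_water_params"))
  if (any(!is.finite(t)) || any(t < 0))
    stop("time must be finite and >= 0")
  rhs <- function(tt, y, parms)
    list(enrichment_ode_rhs(tt, y, p, c, bw))
  ts <- sort(unique(c(0, bw$tau, t)))
  up <- ts[ts <= bw$tau]
  down <- ts[ts >= bw$tau]
  sol <- numeric(length(ts))
  out <- deSolve::lsoda(c(L = 0), times = up, func = rhs, parms = NULL,
                        rtol = rtol, atol = atol)
  sol[seq_along(up)] <- out[, 2]
  if (length(down) > 1) {
    L_tau <- unname(sol[match(bw$tau, ts)])
    out <- deSolve::lsoda(c(L = L_tau), times = down, func = rhs,
                          parms = NULL, rtol = rtol, atol = atol)
    sol[match(down, ts)] <- out[, 2]
  }
  sol[match(t, ts)]
}

#' Label enrichment of a kinetically heterogeneous population
#'
#' Total enrichment of a mixture of subpopulations,
#' \eqn{L(t) = \sum_i \alpha_i L_i(t)}, with each \eqn{L_i} given by
#' [enrichment_closed_form()] at rate \eqn{p_i}.
#'
#' @param t time in days (vectorized).
#' @param model a [kinetic_model()].
#' @param bw a [body_water_params()] object.
#' @return Numeric vector of enrichment fractions.
#' @export
mixture_enrichment <- function(t, model, bw) {
  stopifnot(inherits(model, "kinetic_model"))
  pops <- model$populations
  out <- numeric(length(t))
  for (i in seq_len(nrow(pops))) {
    out <- out + pops$alpha[i] *
      enrichment_closed_form(t, pops$p[i], model$c, bw)
  }
  out
}
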