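#' Variance-stabilizing transform for enrichment fractions
#'
#' Enrichment data are fractions, so the arcsine-square-root transform
#' \eqn{z = \arcsin\sqrt{x}} is applied before least-squares fitting to
#' stabilize the variance. Values outside \[0, 1\] (possible through
#' measurement noise) are clamped before transforming; the number of
#' clamped values is attached as attribute `n_clamped` so pipeline logs
#' can report it.
#'
#' @param x numeric vector of fractions (finite).
#' @return Transformed values in \[0, pi/2\], with attribute `n_clamped`.
#' @seealso [variance_unstabilize()]
#' @export
#' @examples
#' variance_stabilize(c(0, 0.5, 1))  # 0, pi/4, pi/2
variance_stabilize <- function(x) {
  if (any(!is.finite(x))) stop("input to variance_stabilize must be finite")
  n_clamped <- sum(x < 0 | x > 1)
  z <- asin(sqrt(clamp01(x)))
  attr(z, "n_clamped") <- n_clamped
  z
}

#' Back-transform from the arcsine-square-root scale
#'
#' Inverse of [variance_stabilize()]: \eqn{x = \sin^2 z}, with `z` clamped
#' to \[0, pi/2\] first so the result is a valid fraction (used when
#' bootstrap pseudo-observations fall outside the transform's range).
#'
#' @param z numeric vector on the transformed scale.
#' @return Fractions in \[0, 1\], with attribute `n_clamped` counting
#'   values that were clamped.
#' @export
variance_unstabilize <- function(z) {
  if (any(!is.finite(z))) stop("input to variance_unstabilize must be finite")
  n_clamped <- sum(z < 0 | z > pi / 2)
  x <- sin(pmin(pmax(z, 0), pi / 2))^2
  attr(x, "n_clamped") <- n_clamped
  x
}
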