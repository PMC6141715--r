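# Internal helpers shared across the fitting and simulation code.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All randomized package functions go
# through this, so they are reproducible and never disturb the session RNG.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream index, kept within
# 32-bit integer range.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 7919) %% 2147483629) + 1L
}

# Stick-breaking map: k-1 unconstrained logits -> k simplex weights.
alpha_from_stick <- function(q) {
  k <- length(q) + 1
  if (k == 1) return(1)
  a <- numeric(k)
  rem <- 1
  for (i in seq_len(k - 1)) {
    a[i] <- rem * stats::plogis(q[i])
    rem <- rem - a[i]
  }
  a[k] <- rem
  a
}

# Inverse stick-breaking (for warm starts); alpha entries are floored away
# from 0/1 so the logits stay finite.
stick_from_alpha <- function(alpha) {
  k <- length(alpha)
  if (k == 1) return(numeric(0))
  alpha <- pmin(pmax(alpha, 1e-8), 1 - 1e-8)
  alpha <- alpha / sum(alpha)
  q <- numeric(k - 1)
  rem <- 1
  for (i in seq_len(k - 1)) {
    frac <- pmin(pmax(alpha[i] / rem, 1e-8), 1 - 1e-8)
    q[i] <- stats::qlogis(frac)
    rem <- rem - alpha[i]
  }
  q
}

# Map a row of uniforms (from a Latin hypercube) to a uniform draw on the
# simplex via the stick-breaking Beta quantiles.
simplex_from_uniform <- function(u) {
  k <- length(u) + 1
  if (k == 1) return(1)
  a <- numeric(k)
  rem <- 1
  for (i in seq_len(k - 1)) {
    a[i] <- rem * (1 - (1 - u[i])^(1 / (k - i)))
    rem <- rem - a[i]
  }
  a[k] <- rem
  a
}

# Percentile interval using inverse-ECDF (type 1) quantiles, so that with
# two replicates the interval is exactly (min, max).
percentile_ci <- function(x, level = 0.95) {
  x <- x[is.finite(x)]
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  stats::quantile(x, probs = probs, type = 1, names = FALSE)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)
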