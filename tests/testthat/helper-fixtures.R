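# Shared fixtures: everything is generated in code, no stored data.

fixture_bw <- function() body_water_params(f = 0.04, delta = 0.1, tau = 28)

# Sacrifice schedule of the default cross-sectional design, two animals
# per time point.
fixture_times <- function() rep(seq(3, 67, by = 4), each = 2)

# Scaled observations for one cell population generated from a kinetic
# model (unit plateau), with optional Gaussian noise on the transformed
# scale.
make_scaled_obs <- function(alpha, p, bw = fixture_bw(), sd = 0,
                            seed = 1, times = fixture_times(),
                            compartment = "blood", subset = "cd4_memory") {
  model <- kinetic_model(alpha, p, c = 1 / bw$f)
  v <- mixture_enrichment(times, model, bw)
  if (sd > 0) {
    v <- deulabel:::with_seed(seed, {
      z <- asin(sqrt(pmin(pmax(v, 0), 1))) + stats::rnorm(length(v), 0, sd)
      sin(pmin(pmax(z, 0), pi / 2))^2
    })
  }
  data.frame(subject_id = sprintf("an%02d", seq_along(times)),
             time_days = times, compartment = compartment, subset = subset,
             value = v, scaled = TRUE, stringsAsFactors = FALSE)
}

# Raw (unscaled) granulocyte observations from a fast population with a
# given asymptote.
make_granulocyte_obs <- function(asymptote = 0.068, p_g = 0.3, delay = 0,
                                 bw = fixture_bw(), sd = 0, seed = 1,
                                 times = fixture_times()) {
  v <- asymptote * deulabel:::unit_enrichment(pmax(times - delay, 0), p_g,
                                              bw$delta, bw$tau)
  if (sd > 0) {
    v <- deulabel:::with_seed(seed, {
      z <- asin(sqrt(pmin(pmax(v, 0), 1))) + stats::rnorm(length(v), 0, sd)
      sin(pmin(pmax(z, 0), pi / 2))^2
    })
  }
  data.frame(subject_id = sprintf("an%02d", seq_along(times)),
             time_days = times, compartment = "blood",
             subset = "granulocyte", value = v, scaled = FALSE,
             stringsAsFactors = FALSE)
}

# Noise-free plasma observations on a dense schedule.
make_plasma_obs <- function(bw = fixture_bw(), sd = 0, seed = 1,
                            times = c(1, 3, 5, 7, 10, 14, 21, 28, 31, 35,
                                      42, 49, 56, 63)) {
  v <- body_water_enrichment(times, bw)
  if (sd > 0) {
    v <- deulabel:::with_seed(seed, {
      z <- asin(sqrt(pmin(pmax(v, 0), 1))) + stats::rnorm(length(v), 0, sd)
      sin(pmin(pmax(z, 0), pi / 2))^2
    })
  }
  data.frame(subject_id = "pool", time_days = times, compartment = "none",
             subset = "plasma", value = v, scaled = FALSE,
             stringsAsFactors = FALSE)
}
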