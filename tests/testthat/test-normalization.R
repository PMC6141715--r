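test_that("granulocyte asymptote and rate are recovered from noiseless data", {
  bw <- fixture_bw()
  obs <- make_granulocyte_obs(asymptote = 0.068, p_g = 0.3)
  g <- fit_granulocyte_asymptote(obs, bw)
  expect_lt(abs(g$asymptote - 0.068) / 0.068, 1e-4)
  expect_lt(abs(g$p_g - 0.3) / 0.3, 1e-4)
  expect_identical(g$delay, 0)
  expect_false(g$degenerate)
  # allowing a delay on data generated without one changes nothing material
  g_delay <- fit_granulocyte_asymptote(obs, bw, allow_delay = TRUE)
  expect_lt(abs(g_delay$asymptote - g$asymptote) / g$asymptote, 1e-2)
  expect_lt(g_delay$delay, 0.5)
})

test_that("granulocyte fit rejects under-identified or degenerate inputs", {
  bw <- fixture_bw()
  obs <- make_granulocyte_obs()
  expect_error(fit_granulocyte_asymptote(obs[1:3, ], bw),
               "under-identified")
  up_only <- obs[obs$time_days <= bw$tau, ]
  expect_error(fit_granulocyte_asymptote(up_only, bw), "down-labeling")
  zero <- obs
  zero$value <- 0
  expect_warning(g0 <- fit_granulocyte_asymptote(zero, bw), "degenerate")
  expect_true(g0$degenerate)
  expect_error(scale_enrichment(make_scaled_obs(1, 0.02), g0))
})

test_that("scaling divides by the asymptote and is reversible", {
  g <- list(asymptote = 0.04, degenerate = FALSE)
  obs <- make_granulocyte_obs(asymptote = 0.068)
  obs$subset <- "cd8_memory"
  obs$value[1] <- 0.02
  obs$value[2] <- 0
  scaled <- scale_enrichment(obs, g)
  expect_identical(scaled$value[1], 0.5)
  expect_identical(scaled$value[2], 0)
  expect_true(all(scaled$scaled))
  # un-scaling reproduces the input (to one ulp of the division)
  expect_equal(scaled$value * g$asymptote, obs$value, tolerance = 1e-14)
  # refusing to scale twice
  expect_error(scale_enrichment(scaled, g), "already scaled")
})

test_that("scaled granulocytes refitted with unit amplitude give the same rate", {
  bw <- fixture_bw()
  obs <- make_granulocyte_obs(asymptote = 0.068, p_g = 0.3)
  g <- fit_granulocyte_asymptote(obs, bw)
  scaled <- scale_enrichment(obs, g)
  refit <- fit_kinetic_model(scaled, 1, bw, seed = 2)
  expect_lt(abs(refit$model$populations$p - g$p_g), 1e-6)
})
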