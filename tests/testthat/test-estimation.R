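test_that("the arcsine-square-root transform and its inverse behave", {
  expect_identical(as.numeric(variance_stabilize(0)), 0)
  expect_equal(as.numeric(variance_stabilize(1)), pi / 2)
  expect_equal(as.numeric(variance_stabilize(0.5)), pi / 4)
  expect_equal(as.numeric(variance_stabilize(0.5)), 0.7854, tolerance = 1e-4)
  z <- variance_stabilize(c(-0.01, 0.3, 1.02))
  expect_identical(attr(z, "n_clamped"), 2L)
  expect_error(variance_stabilize(c(0.1, NA)), "finite")
  x <- c(0, 0.2, 0.77, 1)
  expect_equal(as.numeric(variance_unstabilize(as.numeric(variance_stabilize(x)))), x)
})

test_that("body-water parameters are recovered from noiseless plasma data", {
  bw <- fixture_bw()
  obs <- make_plasma_obs(bw)
  fit <- fit_body_water(obs, tau = 28)
  expect_lt(abs(fit$bw$f - 0.04), 1e-6)
  expect_lt(abs(fit$bw$delta - 0.1), 1e-6)
  expect_equal(sum(fit$residuals^2), fit$rss, tolerance = 1e-10)
  fit_fixed <- fit_body_water(obs, tau = 28, fix_f = 0.04)
  expect_lt(abs(fit_fixed$bw$delta - 0.1), 1e-6)
  expect_true(fit_fixed$fixed_f)
})

test_that("body-water fitting rejects data that cannot identify the curve", {
  bw <- fixture_bw()
  obs <- make_plasma_obs(bw)
  expect_error(fit_body_water(obs[obs$time_days == 14, ], tau = 28),
               "under-identified")
  expect_error(fit_body_water(obs[obs$time_days <= 28, ], tau = 28),
               "under-identified")
  zero <- obs
  zero$value <- 0
  expect_error(fit_body_water(zero, tau = 28), "degenerate")
})

test_that("kinetic fits recover noiseless truths across the rate range", {
  bw <- fixture_bw()
  for (p_true in c(0.002, 0.02, 0.2)) {
    obs <- make_scaled_obs(1, p_true)
    fit <- fit_kinetic_model(obs, 1, bw)
    expect_lt(abs(fit$model$populations$p - p_true) / p_true, 1e-5)
  }
  obs <- make_scaled_obs(1, 0.02)
  fit <- fit_kinetic_model(obs, 1, bw)
  expect_equal(fit$lifespan, 50, tolerance = 1e-5)
  expect_equal(fit$lifespan, 1 / fit$avg_turnover, tolerance = 1e-12)
  expect_equal(sum(fit$residuals^2), fit$rss, tolerance = 1e-10)
})

test_that("an extra subpopulation collapses on kinetically homogeneous data", {
  bw <- fixture_bw()
  obs <- make_scaled_obs(1, 0.02)
  fit2 <- fit_kinetic_model(obs, 2, bw, seed = 3)
  expect_lt(abs(fit2$avg_turnover - 0.02) / 0.02, 1e-4)
  pops <- fit2$model$populations
  collapsed <- min(pops$alpha) < 1e-3 ||
    abs(pops$p[1] - pops$p[2]) / max(pops$p) < 1e-2
  expect_true(collapsed)
})

test_that("two well-separated subpopulations are recovered from noiseless data", {
  bw <- fixture_bw()
  obs <- make_scaled_obs(c(0.7, 0.3), c(0.05, 0.01))
  fit <- fit_kinetic_model(obs, 2, bw, seed = 5)
  expect_lt(abs(fit$model$populations$p[1] - 0.05) / 0.05, 0.01)
  expect_lt(abs(fit$model$populations$p[2] - 0.01) / 0.01, 0.01)
  expect_lt(abs(fit$model$populations$alpha[1] - 0.7), 0.01)
  expect_lt(abs(fit$avg_turnover - 0.038) / 0.038, 0.01)
})

test_that("estimates are invariant to observation order and under-identification errors", {
  bw <- fixture_bw()
  obs <- make_scaled_obs(c(0.6, 0.4), c(0.06, 0.008), sd = 0.02, seed = 9)
  fit <- fit_kinetic_model(obs, 2, bw, seed = 4)
  perm <- deulabel:::with_seed(17, sample(nrow(obs)))
  fit_perm <- fit_kinetic_model(obs[perm, ], 2, bw, seed = 4)
  expect_lt(abs(fit$avg_turnover - fit_perm$avg_turnover), 1e-12)
  expect_lt(abs(fit$rss - fit_perm$rss), 1e-12)
  expect_error(fit_kinetic_model(obs[1:4, ], 3, bw), "under-identified")
  expect_error(fit_kinetic_model(transform(obs, scaled = FALSE), 1, bw),
               "scaled")
})

test_that("stepwise selection returns a one-row trace when capped at n = 1", {
  bw <- fixture_bw()
  obs <- make_scaled_obs(1, 0.02, sd = 0.02, seed = 2)
  sel <- select_n_subpopulations(obs, bw, max_n = 1, seed = 2)
  expect_identical(nrow(sel$trace), 1L)
  expect_identical(sel$fit$n_subpops, 1L)
  expect_true(sel$trace$accepted[1])
})

test_that("bootstrap intervals are deterministic and respect the percentile definition", {
  bw <- fixture_bw()
  obs <- make_scaled_obs(1, 0.02, sd = 0.02, seed = 21)
  fit <- fit_kinetic_model(obs, 1, bw, seed = 6)
  b1 <- bootstrap_confidence(fit, n_boot = 40, seed = 99)
  b2 <- bootstrap_confidence(fit, n_boot = 40, seed = 99)
  expect_identical(b1$ci, b2$ci)
  expect_identical(b1$boot, b2$boot)
  expect_lte(b1$ci$lifespan[1], b1$ci$lifespan[2])
  expect_lte(b1$ci$avg_turnover[1], b1$ci$avg_turnover[2])
  expect_identical(b1$boot_status, "ok")
  # with two replicates the percentile interval is exactly (min, max)
  b_min <- bootstrap_confidence(fit, n_boot = 2, seed = 7)
  expect_identical(as.numeric(b_min$ci$lifespan),
                   as.numeric(range(b_min$boot$lifespan)))
  expect_error(bootstrap_confidence(fit, n_boot = 1), "n_boot")
})

test_that("turnover comparison is centered, antisymmetric, and detects real differences", {
  bw <- fixture_bw()
  obs <- make_scaled_obs(1, 0.02, sd = 0.02, seed = 31)
  fit <- bootstrap_confidence(fit_kinetic_model(obs, 1, bw, seed = 1),
                              n_boot = 50, seed = 11)
  same <- compare_turnover(fit, fit)
  expect_identical(unique(same$diff), 0)
  expect_false(same$excludes_zero)
  # lifespans 30 d vs 120 d, low noise: the difference is unmistakable
  obs_a <- make_scaled_obs(1, 1 / 30, sd = 0.01, seed = 32)
  obs_b <- make_scaled_obs(1, 1 / 120, sd = 0.01, seed = 33)
  fit_a <- bootstrap_confidence(fit_kinetic_model(obs_a, 1, bw, seed = 1),
                                n_boot = 50, seed = 12)
  fit_b <- bootstrap_confidence(fit_kinetic_model(obs_b, 1, bw, seed = 1),
                                n_boot = 50, seed = 13)
  ab <- compare_turnover(fit_a, fit_b)
  ba <- compare_turnover(fit_b, fit_a)
  expect_true(ab$excludes_zero)
  expect_gt(ab$ci[1], 0)
  expect_equal(as.numeric(ab$ci), -rev(as.numeric(ba$ci)))
  no_boot <- fit_kinetic_model(obs_a, 1, bw, seed = 1)
  expect_error(compare_turnover(no_boot, fit_b), "bootstrap")
})
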