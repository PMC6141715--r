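test_that("body-water curve rises to plateau and decays continuously", {
  bw <- fixture_bw()
  expect_identical(body_water_enrichment(0, bw), 0)
  # frozen value: f*(1 - exp(-delta*t)) evaluated directly at t = 28
  expect_equal(body_water_enrichment(28, bw), 0.04 * (1 - exp(-2.8)))
  expect_equal(body_water_enrichment(28, bw), 0.0375676, tolerance = 1e-5)
  # continuity at tau from both branches
  eps <- 1e-9
  expect_lt(abs(body_water_enrichment(bw$tau - eps, bw) -
                  body_water_enrichment(bw$tau + eps, bw)), 1e-9)
  # bounded by the plateau, decays after cessation
  t_grid <- seq(0, 100, by = 0.5)
  s <- body_water_enrichment(t_grid, bw)
  expect_true(all(s <= bw$f + 1e-15) && all(s >= 0))
  expect_true(all(diff(s[t_grid > bw$tau]) < 0))
  expect_error(body_water_enrichment(-1, bw), "time")
})

test_that("closed-form enrichment matches values computed by numerical integration", {
  bw <- fixture_bw()
  expect_identical(enrichment_closed_form(0, 0.02, 1, bw), 0)
  expect_identical(enrichment_closed_form(c(0, 10, 40), 0, 1.7, bw),
                   c(0, 0, 0))
  # frozen value from integrating the ODE with the fitted S(t) as forcing
  expect_equal(enrichment_closed_form(28, 0.02, 1, bw), 0.0120476,
               tolerance = 1e-4)
  # oracle equivalence on a mixed up/down grid for several rates
  t_grid <- seq(0, 84, by = 1.5)
  for (p in c(0.005, 0.02, 0.1, 0.3)) {
    expect_lt(max(abs(enrichment_closed_form(t_grid, p, 1.7, bw) -
                        enrichment_ode(t_grid, p, 1.7, bw))), 1e-6)
  }
})

test_that("enrichment is continuous at tau, bounded, and monotone during intake", {
  bw <- fixture_bw()
  eps <- 1e-10
  for (p in c(0.001, 0.05, bw$delta, 2)) {
    expect_lt(abs(enrichment_closed_form(bw$tau - eps, p, 1.7, bw) -
                    enrichment_closed_form(bw$tau + eps, p, 1.7, bw)),
              1e-10)
    up <- enrichment_closed_form(seq(0, bw$tau, by = 0.25), p, 1.7, bw)
    expect_true(all(diff(up) >= -1e-15))
    all_t <- enrichment_closed_form(seq(0, 120, by = 0.5), p, 1.7, bw)
    expect_true(all(all_t >= 0 & all_t <= 1.7 * bw$f + 1e-12))
  }
})

test_that("fast populations track c*S(t) and fast body water gives simple saturation", {
  bw <- fixture_bw()
  t_grid <- seq(1, 84, by = 1)
  fast <- enrichment_closed_form(t_grid, 10, 1.7, bw)
  expect_lt(max(abs(fast - 1.7 * body_water_enrichment(t_grid, bw))),
            0.02 * 1.7 * bw$f)
  bw_fast <- body_water_params(0.04, 50, 28)
  up <- seq(1, 28, by = 1)
  lab <- enrichment_closed_form(up, 0.05, 1.7, bw_fast)
  expect_lt(max(abs(lab - 1.7 * 0.04 * (1 - exp(-0.05 * up)))),
            0.01 * 1.7 * 0.04)
})

test_that("the p = delta singularity is removable", {
  bw <- fixture_bw()
  t_grid <- seq(0.5, 84, by = 0.5)
  # near the singularity the closed form must agree with the
  # singularity-free numerical ODE solution, with no cancellation blow-up
  for (p in bw$delta * (1 + c(-1e-6, 0, 1e-6))) {
    expect_lt(max(abs(enrichment_closed_form(t_grid, p, 1, bw) -
                        enrichment_ode(t_grid, p, 1, bw))), 1e-8)
  }
  # continuity across the switch to the analytic limit form
  at <- enrichment_closed_form(t_grid, bw$delta, 1, bw)
  for (side in c(-1, 1)) {
    near <- enrichment_closed_form(t_grid, bw$delta * (1 + side * 2e-9),
                                   1, bw)
    expect_lt(max(abs(at - near)), 1e-10)
  }
})

test_that("ODE right-hand side vanishes at equilibrium and for p = 0", {
  bw <- fixture_bw()
  t <- 12
  L_eq <- 1.7 * body_water_enrichment(t, bw)
  expect_equal(enrichment_ode_rhs(t, L_eq, 0.05, 1.7, bw), 0)
  expect_identical(enrichment_ode_rhs(t, 0.01, 0, 1.7, bw), 0)
})

test_that("mixture enrichment is a convex combination of its components", {
  bw <- fixture_bw()
  t_grid <- seq(0, 70, by = 2)
  one <- kinetic_model(1, 0.03, 1.7)
  expect_equal(mixture_enrichment(t_grid, one, bw),
               enrichment_closed_form(t_grid, 0.03, 1.7, bw))
  # splitting a population into two with the same rate changes nothing
  split <- kinetic_model(c(0.4, 0.6), c(0.03, 0.03), 1.7)
  expect_equal(mixture_enrichment(t_grid, split, bw),
               mixture_enrichment(t_grid, one, bw), tolerance = 1e-14)
  # a two-rate mixture lies between its single-rate curves during intake
  mix <- kinetic_model(c(0.7, 0.3), c(0.05, 0.01), 1.7)
  up <- seq(0.5, 28, by = 0.5)
  lo <- enrichment_closed_form(up, 0.01, 1.7, bw)
  hi <- enrichment_closed_form(up, 0.05, 1.7, bw)
  m <- mixture_enrichment(up, mix, bw)
  expect_true(all(m >= lo - 1e-14 & m <= hi + 1e-14))
})

test_that("average turnover and lifespan follow the mixture definition", {
  expect_identical(average_turnover(kinetic_model(1, 0.02)), 0.02)
  m <- kinetic_model(c(0.7, 0.3), c(0.05, 0.01))
  expect_equal(average_turnover(m), 0.038)
  expect_equal(mean_lifespan(m), 1 / 0.038)
  expect_equal(mean_lifespan(kinetic_model(1, 0.02)), 50)
  # invariant to the order populations are supplied in
  m2 <- kinetic_model(c(0.3, 0.7), c(0.01, 0.05))
  expect_identical(mean_lifespan(m2), mean_lifespan(m))
  # convexity: between the extreme rates
  for (s in 1:20) {
    pars <- deulabel:::with_seed(s, list(a = stats::runif(3), p = stats::runif(3, 0, 0.3)))
    a <- pars$a / sum(pars$a)
    m3 <- kinetic_model(a, pars$p)
    expect_gte(average_turnover(m3), min(pars$p))
    expect_lte(average_turnover(m3), max(pars$p))
  }
  expect_error(mean_lifespan(kinetic_model(1, 0)), "undefined")
})

test_that("kinetic models validate and canonicalize their parameters", {
  expect_error(kinetic_model(c(0.5, 0.4), c(0.1, 0.2)), "sum to 1")
  expect_error(kinetic_model(c(1.2, -0.2), c(0.1, 0.2)), "\\[0, 1\\]")
  expect_error(kinetic_model(1, -0.1), ">= 0")
  expect_error(kinetic_model(1, 0.1, c = 0), "> 0")
  m <- kinetic_model(c(0.3, 0.7), c(0.01, 0.05))
  expect_equal(m$populations$p, c(0.05, 0.01))  # descending rate order
  expect_equal(m$populations$alpha, c(0.7, 0.3))
  expect_error(body_water_params(0, 0.1, 28), "f")
  expect_error(body_water_params(0.04, -1, 28), "delta")
})
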