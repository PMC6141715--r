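test_that("study designs validate the cross-sectional sampling plan", {
  d <- study_design()
  expect_identical(length(d$sacrifice_times), 17L)
  expect_identical(d$n_animals, 34L)
  expect_identical(d$tau, 28)
  expect_identical(d$f_drink, 0.04)
  expect_true(any(d$sacrifice_times > d$tau))
  expect_error(study_design(sacrifice_times = c(3, 7, 14)),
               "down-labeling")
  expect_error(study_design(animals_per_time = 0))
})

test_that("the goat-like truth template is deterministic with the reported structure", {
  t1 <- goat_study_truth()
  t2 <- goat_study_truth()
  expect_identical(t1, t2)
  # two kinetic subpopulations for CD4 memory everywhere and blood CD8
  # memory; one for CD8 memory in bone marrow and lymph node
  for (key in c("blood:cd4_memory", "bm:cd4_memory", "ln:cd4_memory",
                "blood:cd8_memory")) {
    expect_identical(nrow(t1$cells[[key]]$populations), 2L)
  }
  for (key in c("bm:cd8_memory", "ln:cd8_memory")) {
    expect_identical(nrow(t1$cells[[key]]$populations), 1L)
  }
  # lifespans of order tens to ~a hundred days for memory subsets
  for (key in grep("memory", names(t1$cells), value = TRUE)) {
    ls <- mean_lifespan(t1$cells[[key]])
    expect_gt(ls, 20); expect_lt(ls, 150)
  }
  # mixture fractions valid
  for (m in t1$cells) expect_equal(sum(m$populations$alpha), 1)
})

test_that("noise-free simulations reproduce the model curves exactly", {
  design <- study_design(noise_sd_transformed = 0)
  truth <- goat_study_truth()
  plasma <- simulate_plasma(design, truth)
  expect_equal(plasma$value,
               body_water_enrichment(plasma$time_days, truth$bw))
  sim <- simulate_study(design, truth)
  obs <- sim$observations
  expect_true(all(obs$value >= 0 & obs$value <= 1))
  key_rows <- obs$compartment == "bm" & obs$subset == "cd8_memory"
  expect_equal(obs$value[key_rows],
               mixture_enrichment(obs$time_days[key_rows],
                                  truth$cells[["bm:cd8_memory"]], truth$bw))
  # transformed-scale residuals against truth are exactly zero
  z_obs <- as.numeric(variance_stabilize(obs$value[key_rows]))
  z_true <- as.numeric(variance_stabilize(
    mixture_enrichment(obs$time_days[key_rows],
                       truth$cells[["bm:cd8_memory"]], truth$bw)))
  expect_identical(z_obs, z_true)
})

test_that("simulated studies are seed-deterministic and cross-sectional", {
  design <- study_design(seed = 42)
  truth <- goat_study_truth()
  s1 <- simulate_study(design, truth)
  s2 <- simulate_study(design, truth)
  expect_identical(s1$observations, s2$observations)
  expect_identical(s1$assignment, s2$assignment)
  s3 <- simulate_study(design, truth, seed = 43)
  expect_false(identical(s1$observations$value, s3$observations$value))
  # every animal contributes cell observations at exactly one time
  cells <- s1$observations[!s1$observations$subset %in% "plasma", ]
  per_animal <- tapply(cells$time_days, cells$subject_id,
                       function(x) length(unique(x)))
  expect_true(all(per_animal == 1))
  expect_identical(length(per_animal), 34L)
})

test_that("plasma fits on simulated noisy data recover the body-water curve", {
  design <- study_design(seed = 7)
  truth <- goat_study_truth()
  plasma <- simulate_plasma(design, truth)
  fit <- fit_body_water(plasma, tau = design$tau)
  expect_lt(abs(fit$bw$f - truth$bw$f) / truth$bw$f, 0.05)
  expect_lt(abs(fit$bw$delta - truth$bw$delta) / truth$bw$delta, 0.05)
})

test_that("doubling the animals per time point tightens bootstrap intervals", {
  truth <- goat_study_truth()
  width <- function(apt, seed) {
    design <- study_design(animals_per_time = apt, seed = seed)
    sim <- simulate_study(design, truth)
    obs <- sim$observations
    gran <- fit_granulocyte_asymptote(obs, truth$bw, seed = seed)
    cell <- obs[obs$compartment == "bm" & obs$subset == "cd8_memory", ]
    fit <- fit_kinetic_model(scale_enrichment(cell, gran), 1, truth$bw,
                             seed = seed)
    fit <- bootstrap_confidence(fit, n_boot = 60, seed = seed + 1000)
    diff(as.numeric(fit$ci$lifespan))
  }
  w2 <- vapply(1:20, function(s) width(2, s), numeric(1))
  w4 <- vapply(1:20, function(s) width(4, s), numeric(1))
  expect_lt(mean(w4), mean(w2))
})
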