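#' Cross-sectional labeling study design
#'
#' Sampling plan of a heavy-water labeling study in which each animal is
#' sacrificed at a single time point (cross-sectional design), so the
#' population labeling curve is assembled across animals. Defaults mirror
#' the goat study template: 4% heavy water in the drinking water for 28
#' days, 17 sacrifice time points at 4-day spacing spanning up- and
#' down-labeling, and 2 animals per time point (34 animals). The actual
#' sacrifice and plasma sampling days of that study are not published;
#' these defaults are stated placeholders with the same structure.
#'
#' @param f_drink heavy-water fraction in the drinking water.
#' @param tau label duration in days.
#' @param sacrifice_times days at which animals are sacrificed; at least
#'   one must exceed `tau` so down-labeling is observable.
#' @param animals_per_time animals sacrificed per time point.
#' @param plasma_sampling days at which plasma is drawn from each animal
#'   while it is alive (its sacrifice day is always included).
#' @param noise_sd_transformed Gaussian measurement noise SD on the
#'   arcsine-square-root scale.
#' @param seed integer seed for the simulator.
#' @return An object of class `study_design`.
#' @export
study_design <- function(f_drink = 0.04, tau = 28,
                         sacrifice_times = seq(3, 67, by = 4),
                         animals_per_time = 2,
                         plasma_sampling = c(1, 3, 5, 7, 10, 14, 21, 28,
                                             31, 35, 42, 49, 56, 63),
                         noise_sd_transformed = 0.02, seed = 1L) {
  stopifnot(f_drink > 0, f_drink <= 1, tau > 0,
            length(sacrifice_times) >= 2, all(sacrifice_times >= 0),
            animals_per_time >= 1, all(plasma_sampling >= 0),
            noise_sd_transformed >= 0)
  if (!any(sacrifice_times > tau))
    stop("at least one sacrifice time must exceed tau so that ",
         "down-labeling is observable")
  structure(list(
    f_drink = f_drink, tau = tau,
    sacrifice_times = sort(sacrifice_times),
    animals_per_time = as.integer(animals_per_time),
    n_animals = as.integer(animals_per_time) * length(sacrifice_times),
    plasma_sampling = sort(unique(plasma_sampling)),
    noise_sd_transformed = noise_sd_transformed,
    seed = as.integer(seed)
  ), class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(
    "Cross-sectional labeling design: %g%% heavy water for %g d,\n  %d sacrifice times (%g-%g d), %d animals/time (%d total), noise SD %.3g\n",
    100 * x$f_drink, x$tau, length(x$sacrifice_times),
    min(x$sacrifice_times), max(x$sacrifice_times),
    x$animals_per_time, x$n_animals, x$noise_sd_transformed))
  invisible(x)
}

#' Ground-truth kinetics template for a goat-like labeling study
#'
#' A fixed, deterministic truth specification with the structure and
#' plausible magnitudes of memory and naive T-cell kinetics in blood, bone
#' marrow and lymph node: average lifespans of order tens to a hundred
#' days; two kinetically distinct subpopulations for CD4 memory cells in
#' all three compartments and for CD8 memory cells in blood; a single
#' population for CD8 memory cells in bone marrow and lymph node and for
#' the (slower) naive subsets. The body-water curve uses the nominal 4%
#' drinking-water fraction, and the amplification factor is 1.7, giving a
#' granulocyte asymptote of 0.068.
#'
#' @return An object of class `truth_spec`: `bw` (a
#'   [body_water_params()]), `cells` (named list `"compartment:subset"` of
#'   [kinetic_model()]s), and `granulocyte` (`p_g`, `asymptote`, `delay`).
#' @export
goat_study_truth <- function() {
  cc <- 1.7
  cells <- list(
    "blood:cd4_memory" = kinetic_model(c(0.5, 0.5), c(0.040, 0.006), cc),
    "bm:cd4_memory"    = kinetic_model(c(0.5, 0.5), c(0.034, 0.006), cc),
    "ln:cd4_memory"    = kinetic_model(c(0.5, 0.5), c(0.031, 0.006), cc),
    "blood:cd8_memory" = kinetic_model(c(0.5, 0.5), c(0.0545, 0.008), cc),
    "bm:cd8_memory"    = kinetic_model(1, 1 / 54, cc),
    "ln:cd8_memory"    = kinetic_model(1, 1 / 136, cc),
    "blood:cd4_naive"  = kinetic_model(1, 1 / 180, cc),
    "bm:cd4_naive"     = kinetic_model(1, 1 / 180, cc),
    "ln:cd4_naive"     = kinetic_model(1, 1 / 180, cc),
    "blood:cd8_naive"  = kinetic_model(1, 1 / 150, cc),
    "bm:cd8_naive"     = kinetic_model(1, 1 / 150, cc),
    "ln:cd8_naive"     = kinetic_model(1, 1 / 150, cc)
  )
  bw <- body_water_params(f = 0.04, delta = 0.1, tau = 28)
  structure(list(bw = bw, cells = cells,
                 granulocyte = list(p_g = 0.3, asymptote = cc * bw$f,
                                    delay = 0)),
            class = "truth_spec")
}

#' @export
print.truth_spec <- function(x, ...) {
  cat("Ground-truth kinetics specification\n")
  print(x$bw)
  cat(sprintf("Granulocytes: p_g %.3g /day, asymptote %.4g, delay %g d\n",
              x$granulocyte$p_g, x$granulocyte$asymptote,
              x$granulocyte$delay))
  for (nm in names(x$cells)) {
    m <- x$cells[[nm]]
    cat(sprintf("  %-18s n=%d, lifespan %.4g d\n", nm,
                nrow(m$populations), mean_lifespan(m)))
  }
  invisible(x)
}

# Deterministic (seeded) assignment of animal ids to sacrifice times.
animal_assignment <- function(design) {
  ids <- sprintf("goat%02d", seq_len(design$n_animals))
  slots <- rep(design$sacrifice_times, each = design$animals_per_time)
  perm <- with_seed(child_seed(design$seed, 1), sample(design$n_animals))
  data.frame(subject_id = ids[perm], sacrifice_day = slots,
             stringsAsFactors = FALSE)
}

add_transformed_noise <- function(values, sd) {
  if (sd == 0) return(values)
  z <- asin(sqrt(clamp01(values))) + stats::rnorm(length(values), 0, sd)
  sin(pmin(pmax(z, 0), pi / 2))^2
}

#' Simulate plasma heavy-water measurements
#'
#' Evaluates the true body-water curve at each animal's plasma sampling
#' days (those not after its sacrifice day, plus the sacrifice day itself)
#' and adds Gaussian noise on the arcsine-square-root scale,
#' back-transformed and clamped to \[0, 1\].
#'
#' @param design a [study_design()].
#' @param truth a truth specification (see [goat_study_truth()]).
#' @param seed integer seed; defaults to the design's seed.
#' @return Observation data frame (`subset = "plasma"`,
#'   `compartment = "none"`, `scaled = FALSE`).
#' @export
simulate_plasma <- function(design, truth, seed = design$seed) {
  stopifnot(inherits(design, "study_design"), inherits(truth, "truth_spec"))
  assign <- animal_assignment(design)
  rows <- lapply(seq_len(nrow(assign)), function(i) {
    days <- unique(c(design$plasma_sampling[
      design$plasma_sampling <= assign$sacrifice_day[i]],
      assign$sacrifice_day[i]))
    data.frame(subject_id = assign$subject_id[i], time_days = days,
               compartment = "none", subset = "plasma",
               value = body_water_enrichment(days, truth$bw),
               scaled = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$value <- with_seed(child_seed(seed, 2),
                         add_transformed_noise(out$value,
                                               design$noise_sd_transformed))
  out
}

#' Simulate a complete cross-sectional labeling study
#'
#' Generates plasma, granulocyte, and cell-subset enrichment observations
#' under a known ground truth. Each animal contributes cell and
#' granulocyte observations only at its sacrifice day (cross-sectional
#' design); plasma is sampled longitudinally up to sacrifice. Cell values
#' are raw (unscaled) mixture enrichments, whose plateau is governed by the
#' amplification factor and plasma plateau of the truth; granulocyte
#' values follow a single fast population with the truth's asymptote and
#' optional maturation delay. All noise is Gaussian on the
#' arcsine-square-root scale. The returned object carries the truth and
#' design so recovery against ground truth can be assessed (see
#' [write_study()] for the sidecar file).
#'
#' @inheritParams simulate_plasma
#' @return An object of class `simulated_study`: `observations` (one data
#'   frame with plasma + granulocyte + cell rows), `truth`, `design`, and
#'   `assignment` (animal-to-time table).
#' @export
simulate_study <- function(design, truth, seed = design$seed) {
  stopifnot(inherits(design, "study_design"), inherits(truth, "truth_spec"))
  plasma <- simulate_plasma(design, truth, seed = seed)
  assign <- animal_assignment(design)
  g <- truth$granulocyte
  gran <- data.frame(
    subject_id = assign$subject_id, time_days = assign$sacrifice_day,
    compartment = "blood", subset = "granulocyte",
    value = g$asymptote * unit_enrichment(
      pmax(assign$sacrifice_day - g$delay, 0), g$p_g,
      truth$bw$delta, truth$bw$tau),
    scaled = FALSE, stringsAsFactors = FALSE)
  cell_rows <- lapply(names(truth$cells), function(nm) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    data.frame(
      subject_id = assign$subject_id, time_days = assign$sacrifice_day,
      compartment = parts[1], subset = parts[2],
      value = mixture_enrichment(assign$sacrifice_day, truth$cells[[nm]],
                                 truth$bw),
      scaled = FALSE, stringsAsFactors = FALSE)
  })
  cells <- do.call(rbind, c(list(gran), cell_rows))
  cells$value <- with_seed(child_seed(seed, 3),
                           add_transformed_noise(cells$value,
                                                 design$noise_sd_transformed))
  obs <- rbind(plasma, cells)
  rownames(obs) <- NULL
  structure(list(observations = obs, truth = truth, design = design,
                 assignment = assign),
            class = "simulated_study")
}
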