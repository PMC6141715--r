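#' Run the full labeling-kinetics pipeline
#'
#' Executes the analysis stages in the order the method prescribes:
#' fit the plasma body-water curve; fit the granulocyte asymptote; scale
#' all cell-subset enrichment by it; per (compartment, subset), select the
#' number of kinetic subpopulations stepwise and attach residual-bootstrap
#' confidence intervals; finally compare average turnover rates pairwise
#' across compartments within each subset. Any stage error halts the run
#' with a stage-labeled message.
#'
#' @param plasma plasma observations: a data frame or a CSV path (see
#'   [read_observations()]).
#' @param cells cell observations (granulocyte rows included): data frame
#'   or CSV path.
#' @param config a [run_config()].
#' @return An object of class `pipeline_report`: `config`, `body_water`
#'   (fit), `granulocyte` (fit), `fits` (named list per
#'   `"compartment:subset"`, each with the selected [kinetic_fit] and the
#'   selection trace), `comparisons` (per subset, pairwise across
#'   compartments), `log` (character vector), `checksums`, and `version`.
#'   When `config$out_dir` is set, `report.json`,
#'   `bootstrap_replicates.csv` and `run.log` are written there; the JSON
#'   is fully determined by the inputs and seed (timestamps go only to the
#'   log).
#' @export
run_pipeline <- function(plasma, cells, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  log <- character()
  note <- function(...) {
    log[[length(log) + 1]] <<- sprintf(...)
    invisible(NULL)
  }
  checksums <- list()
  load_obs <- function(x, what) {
    if (is.character(x)) {
      checksums[[what]] <<- unname(tools::md5sum(x))
      read_observations(x)
    } else {
      checksums[[what]] <<- NA_character_
      validate_observations(x, what)
      x
    }
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }

  plasma_obs <- stage("read-plasma", load_obs(plasma, "plasma"))
  cell_obs <- stage("read-cells", load_obs(cells, "cells"))
  note("pipeline seed %d; %d plasma rows, %d cell rows",
       config$seed, nrow(plasma_obs), nrow(cell_obs))

  bw_fit <- stage("fit-body-water", fit_body_water(
    plasma_obs, tau = config$tau,
    fix_f = if (config$fix_f) config$f_drink else NULL,
    seed = child_seed(config$seed, 1)))
  note("body water: f = %.6g, delta = %.6g /day, rss = %.6g",
       bw_fit$bw$f, bw_fit$bw$delta, bw_fit$rss)

  gran_fit <- stage("fit-granulocytes", fit_granulocyte_asymptote(
    cell_obs, bw_fit$bw, allow_delay = config$granulocyte_delay,
    seed = child_seed(config$seed, 2)))
  note("granulocyte asymptote: %.6g (p_g = %.5g /day, delay = %.3g d)",
       gran_fit$asymptote, gran_fit$p_g, gran_fit$delay)

  subsets_cells <- cell_obs[cell_obs$subset %in%
                              c("cd4_memory", "cd8_memory",
                                "cd4_naive", "cd8_naive"), , drop = FALSE]
  if (nrow(subsets_cells) == 0)
    stop("pipeline stage [scale] failed: no cell-subset observations",
         call. = FALSE)
  scaled <- stage("scale", scale_enrichment(subsets_cells, gran_fit))
  note("scaled %d cell observations by asymptote %.6g",
       nrow(scaled), gran_fit$asymptote)

  groups <- unique(scaled[c("compartment", "subset")])
  groups <- groups[order(groups$subset, groups$compartment), , drop = FALSE]
  fits <- list()
  for (i in seq_len(nrow(groups))) {
    comp <- groups$compartment[i]; sub <- groups$subset[i]
    key <- paste(comp, sub, sep = ":")
    gobs <- scaled[scaled$compartment == comp & scaled$subset == sub, ,
                   drop = FALSE]
    sel <- stage(paste0("select-", key), select_n_subpopulations(
      gobs, bw_fit$bw, max_n = config$max_n_subpops,
      starts = config$n_starts, seed = child_seed(config$seed, 10 + i),
      alpha = config$selection_alpha,
      min_rel_change = config$selection_min_rel_change))
    fit <- sel$fit
    if (config$n_boot >= 2) {
      fit <- stage(paste0("bootstrap-", key), bootstrap_confidence(
        fit, n_boot = config$n_boot,
        seed = child_seed(config$seed, 1000 + i)))
      note("%s: n = %d, lifespan %.5g d, 95%% CI [%.5g, %.5g] (%d boot, %d failed, %d clamped)",
           key, fit$n_subpops, fit$lifespan, fit$ci$lifespan[1],
           fit$ci$lifespan[2], fit$n_boot, fit$n_failed, fit$boot_clamped)
    } else {
      note("%s: n = %d, lifespan %.5g d (bootstrap skipped)",
           key, fit$n_subpops, fit$lifespan)
    }
    fits[[key]] <- list(fit = fit, trace = sel$trace)
  }

  comparisons <- list()
  if (config$n_boot >= 2) {
    for (sub in unique(groups$subset)) {
      comps <- groups$compartment[groups$subset == sub]
      if (length(comps) < 2) next
      pairs <- utils::combn(sort(comps), 2, simplify = FALSE)
      for (pr in pairs) {
        keyA <- paste(pr[1], sub, sep = ":")
        keyB <- paste(pr[2], sub, sep = ":")
        cmp <- compare_turnover(fits[[keyA]]$fit, fits[[keyB]]$fit)
        comparisons[[sub]][[paste(pr[1], "vs", pr[2])]] <- cmp
        note("compare %s: %s vs %s, diff CI [%.5g, %.5g]%s", sub, pr[1],
             pr[2], cmp$ci[1], cmp$ci[2],
             if (cmp$excludes_zero) " *" else "")
      }
    }
  }

  report <- structure(list(
    config = config, body_water = bw_fit, granulocyte = gran_fit,
    fits = fits, comparisons = comparisons, log = log,
    checksums = checksums,
    version = as.character(utils::packageVersion("deulabel"))
  ), class = "pipeline_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Labeling-kinetics pipeline report\n")
  cat(sprintf("  body water: f = %.5g, delta = %.5g /day\n",
              x$body_water$bw$f, x$body_water$bw$delta))
  cat(sprintf("  granulocyte asymptote: %.5g\n", x$granulocyte$asymptote))
  for (key in names(x$fits)) {
    fit <- x$fits[[key]]$fit
    ci_txt <- if (!is.null(fit$ci))
      sprintf(" [%.4g, %.4g]", fit$ci$lifespan[1], fit$ci$lifespan[2])
    else ""
    cat(sprintf("  %-18s n = %d, lifespan %.4g d%s\n", key,
                fit$n_subpops, fit$lifespan, ci_txt))
  }
  invisible(x)
}

# Serialize a pipeline report deterministically (no timestamps) to
# report.json, plus bootstrap replicates as CSV and the run log as text.
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fit_plain <- function(entry) {
    fit <- entry$fit
    out <- list(
      n_subpops = fit$n_subpops,
      model = list(alpha = fit$model$populations$alpha,
                   p = fit$model$populations$p, c = fit$model$c),
      rss = fit$rss, avg_turnover = fit$avg_turnover,
      lifespan = fit$lifespan, seed = fit$seed, starts = fit$starts,
      trace = entry$trace
    )
    if (!is.null(fit$ci)) {
      out$ci <- lapply(fit$ci, as.numeric)
      out$n_boot <- fit$n_boot
      out$n_failed <- fit$n_failed
      out$boot_status <- fit$boot_status
    }
    out
  }
  plain <- list(
    version = report$version,
    config = unclass(report$config),
    checksums = report$checksums,
    body_water = list(f = report$body_water$bw$f,
                      delta = report$body_water$bw$delta,
                      tau = report$body_water$bw$tau,
                      rss = report$body_water$rss,
                      fixed_f = report$body_water$fixed_f),
    granulocyte = report$granulocyte[c("asymptote", "p_g", "delay", "rss",
                                       "degenerate")],
    fits = lapply(report$fits, fit_plain),
    comparisons = lapply(report$comparisons, function(sub)
      lapply(sub, function(cmp) list(
        ci = as.numeric(cmp$ci), excludes_zero = cmp$excludes_zero,
        avg_turnover_A = cmp$avg_turnover_A,
        avg_turnover_B = cmp$avg_turnover_B)))
  )
  jsonlite::write_json(plain, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns", na = "null")
  boot_rows <- list()
  for (key in names(report$fits)) {
    b <- report$fits[[key]]$fit$boot
    if (!is.null(b)) boot_rows[[key]] <- cbind(population = key, b)
  }
  if (length(boot_rows) > 0) {
    utils::write.csv(do.call(rbind, boot_rows),
                     file.path(dir, "bootstrap_replicates.csv"),
                     row.names = FALSE)
  }
  writeLines(c(paste("run at", format(Sys.time(), usetz = TRUE)),
               report$log),
             file.path(dir, "run.log"))
  invisible(dir)
}
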