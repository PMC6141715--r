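#' Read an enrichment observation table
#'
#' Reads and strictly validates the plain-CSV observation schema used
#' throughout the pipeline: columns `subject_id` (string), `time_days`
#' (decimal, >= 0), `compartment` (`blood|bm|ln|none`), `subset`
#' (`cd4_memory|cd8_memory|cd4_naive|cd8_naive|granulocyte|plasma`),
#' `value` (decimal fraction), `scaled` (logical). Rows violating the
#' schema are rejected with their row numbers. Enrichment is stored as
#' fractions, never percent; time is days since the first heavy-water
#' intake.
#'
#' @param path path to a CSV file with a header row.
#' @return A validated observation data frame.
#' @seealso [write_observations()]
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "time_days", "compartment", "subset",
                "value", "scaled")
  missing_cols <- setdiff(required, names(obs))
  if (length(missing_cols) > 0)
    stop("parse error in ", path, ": missing column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in c("time_days", "value")) {
    suppressWarnings(num <- as.numeric(obs[[col]]))
    bad <- which(is.na(num) & !is.na(obs[[col]]))
    if (length(bad) > 0)
      stop("parse error in ", path, ": malformed number in '", col,
           "' at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
    obs[[col]] <- num
  }
  if (is.character(obs$scaled))
    obs$scaled <- toupper(obs$scaled) %in% c("TRUE", "T", "1")
  if (is.numeric(obs$scaled)) obs$scaled <- obs$scaled != 0
  obs$subject_id <- as.character(obs$subject_id)
  validate_observations(obs, paste0("'", path, "'"))
  obs[required]
}

#' Write an enrichment observation table
#'
#' Writes the observation schema of [read_observations()] as CSV, with
#' numeric columns printed at full precision (17 significant digits) so a
#' write/read round trip reproduces the values exactly.
#'
#' @param obs observation data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  validate_observations(obs)
  out <- obs[c("subject_id", "time_days", "compartment", "subset",
               "value", "scaled")]
  out$time_days <- formatC(out$time_days, digits = 17, format = "g")
  out$value <- formatC(out$value, digits = 17, format = "g")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulated study with its ground-truth sidecar
#'
#' Writes `observations.csv` (the full observation table),
#' `truth.json` (the generative parameters: body-water curve, per-subset
#' kinetic models, granulocyte parameters) and `design.json` (the sampling
#' plan) into a directory, so simulated datasets are self-describing and
#' recovery against truth can be checked later.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "simulated_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_observations(study$observations, file.path(dir, "observations.csv"))
  truth <- study$truth
  truth_plain <- list(
    bw = unclass(truth$bw),
    cells = lapply(truth$cells, function(m)
      list(alpha = m$populations$alpha, p = m$populations$p, c = m$c)),
    granulocyte = truth$granulocyte
  )
  jsonlite::write_json(truth_plain, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(unclass(study$design), file.path(dir, "design.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Pipeline run configuration
#'
#' Bundles the tunable parameters of [run_pipeline()] with validation.
#' Units: days and per-day rates; enrichment fractions.
#'
#' @param tau label cessation day (experimental constant, never fitted).
#' @param f_drink nominal drinking-water heavy-water fraction (used to
#'   initialize, and optionally fix, the plasma plateau).
#' @param fix_f fix the plasma plateau at `f_drink` instead of fitting it?
#' @param max_n_subpops largest number of kinetic subpopulations
#'   considered by the stepwise selector.
#' @param n_starts multi-start initializations per kinetic fit.
#' @param n_boot bootstrap replicates (0 skips the bootstrap).
#' @param seed integer master seed for the run.
#' @param selection_alpha F-test significance level of the stepwise
#'   selector.
#' @param selection_min_rel_change minimum relative change in average
#'   turnover for an extra subpopulation to be accepted.
#' @param granulocyte_delay co-estimate a granulocyte maturation delay?
#' @param out_dir optional output directory; when set, [run_pipeline()]
#'   writes `report.json`, `bootstrap_replicates.csv` and `run.log` there.
#' @return A list of class `run_config`.
#' @export
run_config <- function(tau = 28, f_drink = 0.04, fix_f = FALSE,
                       max_n_subpops = 3, n_starts = 25, n_boot = 500,
                       seed = 1L, selection_alpha = 0.05,
                       selection_min_rel_change = 0.05,
                       granulocyte_delay = FALSE, out_dir = NULL) {
  stopifnot(tau > 0, f_drink > 0, f_drink <= 1, max_n_subpops >= 1,
            n_starts >= 1, n_boot >= 0, selection_alpha > 0,
            selection_alpha < 1, selection_min_rel_change >= 0)
  structure(list(
    tau = tau, f_drink = f_drink, fix_f = isTRUE(fix_f),
    max_n_subpops = as.integer(max_n_subpops),
    n_starts = as.integer(n_starts), n_boot = as.integer(n_boot),
    seed = as.integer(seed), selection_alpha = selection_alpha,
    selection_min_rel_change = selection_min_rel_change,
    granulocyte_delay = isTRUE(granulocyte_delay), out_dir = out_dir
  ), class = "run_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Fields not present in the file keep their [run_config()] defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A [run_config()] object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("unsupported config format: .", ext,
                   " (use YAML or JSON)")
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}
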