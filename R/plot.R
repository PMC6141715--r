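#' Plot fitted enrichment curves over the data
#'
#' One panel per (compartment, subset): scaled enrichment observations as
#' points, the fitted mixture enrichment curve on a dense time grid, and a
#' vertical marker at the label cessation day. The curve is regenerated
#' from the fitted model with [mixture_enrichment()], so the plotted line
#' is exactly the model the report describes; the curve data are returned
#' so they can be checked without rendering pixels.
#'
#' @param report a [run_pipeline()] result.
#' @param data the scaled (or raw; values are scaled on the fly using the
#'   report's granulocyte asymptote) cell observation data frame.
#' @param out_dir directory for figure files; created if needed.
#' @param format `"png"` or `"svg"`.
#' @return Invisibly, a list with `files` (named character vector of
#'   written paths) and `curves` (named list of data frames `t`,
#'   `enrichment`). Subsets present in the report but absent from `data`
#'   are skipped with a log note (attribute `skipped`).
#' @export
plot_fits <- function(report, data, out_dir, format = c("png", "svg")) {
  stopifnot(inherits(report, "pipeline_report"))
  format <- match.arg(format)
  validate_observations(data, "plot data")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tau <- report$config$tau
  files <- character()
  curves <- list()
  skipped <- character()
  for (key in names(report$fits)) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    pts <- data[data$compartment == parts[1] & data$subset == parts[2], ,
                drop = FALSE]
    if (nrow(pts) == 0) {
      skipped <- c(skipped, key)
      next
    }
    if (!all(pts$scaled))
      pts$value <- pts$value / report$granulocyte$asymptote
    fit <- report$fits[[key]]$fit
    grid <- seq(0, max(pts$time_days) * 1.05, length.out = 200)
    curve <- data.frame(
      t = grid,
      enrichment = mixture_enrichment(grid, fit$model, fit$bw))
    gg <- ggplot2::ggplot(pts, ggplot2::aes(x = time_days, y = value)) +
      ggplot2::geom_vline(xintercept = tau, linetype = "dashed",
                          colour = "grey50") +
      ggplot2::geom_line(data = curve,
                         ggplot2::aes(x = t, y = enrichment),
                         colour = "#2166ac", linewidth = 0.8) +
      ggplot2::geom_point(size = 1.8, alpha = 0.8) +
      ggplot2::labs(
        title = sprintf("%s %s: n = %d, lifespan %.3g d", parts[1],
                        parts[2], fit$n_subpops, fit$lifespan),
        x = "days since start of label intake",
        y = "scaled DNA enrichment") +
      ggplot2::theme_bw()
    file <- file.path(out_dir, sprintf("fit_%s_%s.%s", parts[1], parts[2],
                                       format))
    ggplot2::ggsave(file, gg, width = 5, height = 3.5, dpi = 150)
    files[key] <- file
    curves[[key]] <- curve
  }
  out <- list(files = files, curves = curves)
  attr(out, "skipped") <- skipped
  invisible(out)
}
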