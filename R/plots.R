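# Figures for simulation results.

#' Plot performance criteria across scenarios
#'
#' Line plots of bias, coverage, bias-corrected coverage, power or MSE
#' against the true odds ratio, one line per method. Expects a tibble of
#' stacked [performance_summary()] rows with a `true_or` column (e.g. from
#' running [run_scenario()] over [baseline_scenario()] variants).
#'
#' @param summaries tibble with columns `method`, `true_or` and the metric.
#' @param metric one of `"bias"`, `"coverage"`, `"bias_corrected_coverage"`,
#'   `"power"`, `"mse"`.
#' @return a ggplot object.
#' @export
plot_performance <- function(summaries,
                             metric = c("bias", "coverage",
                                        "bias_corrected_coverage",
                                        "power", "mse")) {
  metric <- match.arg(metric)
  stopifnot(all(c("method", "true_or", metric) %in% names(summaries)))
  gg <- ggplot2::ggplot(
    summaries,
    ggplot2::aes(x = .data$true_or, y = .data[[metric]],
                 colour = .data$method, group = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "true odds ratio", y = gsub("_", " ", metric),
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (metric %in% c("coverage", "bias_corrected_coverage")) {
    gg <- gg + ggplot2::geom_hline(yintercept = 0.95, linetype = 2,
                                   colour = "grey40")
  }
  if (metric == "bias") {
    gg <- gg + ggplot2::geom_hline(yintercept = 0, linetype = 2,
                                   colour = "grey40")
  }
  gg
}

#' Boxplots of relative precision
#'
#' Distribution of per-replicate variance ratios for one or more method
#' pairs, on a log scale with a reference line at 1 (equal precision).
#'
#' @param ratios a tibble from [relative_precision()], or several bound
#'   together (the `comparison` column labels the panels).
#' @return a ggplot object.
#' @export
plot_relative_precision <- function(ratios) {
  stopifnot(all(c("ratio", "comparison") %in% names(ratios)))
  ggplot2::ggplot(ratios,
                  ggplot2::aes(x = .data$comparison, y = .data$ratio)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.3) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey40") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "relative precision (variance ratio)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a scenario result
#'
#' Boxplots of the relative precision of the first listed method against each
#' of the others.
#'
#' @param object an `lv_scenario_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.lv_scenario_result <- function(object, ...) {
  methods <- unique(object$replicates$method)
  if (length(methods) < 2L) {
    stop("autoplot.lv_scenario_result: need at least two methods",
         call. = FALSE)
  }
  ref <- methods[1]
  ratios <- dplyr::bind_rows(
    lapply(methods[-1], function(m) relative_precision(object, ref, m)))
  plot_relative_precision(ratios)
}
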