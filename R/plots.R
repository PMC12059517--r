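#' Violin summaries of spot accuracy and reproducibility by gantry angle
#'
#' Distribution of a per-spot statistic per gantry angle, drawn as violins
#' with an overlaid median and interquartile box — the standard way to
#' screen for angle-dependent systematic machine effects (horizontal beams
#' typically show the worst x accuracy).
#'
#' @param stats An [spot_statistics()] tibble.
#' @param quantity Column to plot (`"mu_x"`, `"sigma_x"`, ...).
#' @return A ggplot object.
#' @export
plot_spot_statistics <- function(stats, quantity = "mu_x") {
  ggplot2::ggplot(stats, ggplot2::aes(
    x = factor(.data$gantry_angle), y = .data[[quantity]]
  )) +
    ggplot2::geom_violin(fill = "steelblue", alpha = 0.6, scale = "width") +
    ggplot2::geom_boxplot(width = 0.12, outlier.shape = NA,
                          fill = "grey20", color = "white") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "gantry angle [deg]", y = quantity) +
    ggplot2::theme_minimal()
}

#' Per-fraction pass-rate series plot
#'
#' Lambda and Gamma pass rates per fraction for one plan and reference.
#'
#' @param object An `lfqa_series` from [build_series()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lfqa_series <- function(object, ...) {
  df <- tidyr::pivot_longer(tidy(object),
                            cols = c("lambda_percent", "gamma_percent"),
                            names_to = "metric", values_to = "pass_rate")
  r <- attr(object, "pearson_r")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction_index,
                                   y = .data$pass_rate,
                                   color = .data$metric,
                                   shape = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "fraction", y = "pass rate [%]",
      title = sprintf("%s vs %s", attr(object, "plan_id"),
                      attr(object, "reference_kind")),
      subtitle = if (is.na(r)) "r undefined" else sprintf("Pearson r = %.2f", r)
    ) +
    ggplot2::theme_minimal()
}

#' Cumulative delivery-time decomposition plot
#'
#' Fraction-wise cumulative spot drill, spot switching and energy switching
#' times for one field, with interlock time shown separately.
#'
#' @param breakdowns Timing tibble from [decompose_field_timing()] /
#'   [decompose_timing()] rows across fractions (one field).
#' @return A ggplot object.
#' @export
plot_timing_breakdown <- function(breakdowns) {
  df <- tidyr::pivot_longer(
    breakdowns,
    cols = c("drill_total", "spot_switch_total", "energy_switch_total",
             "interlock_total"),
    names_to = "component", values_to = "seconds"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction_index,
                                   y = .data$seconds,
                                   color = .data$component,
                                   shape = .data$component)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "fraction", y = "cumulative time [s]") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
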