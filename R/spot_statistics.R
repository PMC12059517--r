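#' Per-spot accuracy, reproducibility and distance accuracy
#'
#' The three elementary statistics computed per spot over the N delivered
#' fractions of a course:
#'
#' * `spot_accuracy()`: the sample mean deviation of the logged values from
#'   the planned value, `mu_s = mean(L_i - P)` — the accuracy of a spot
#'   parameter (position coordinate or MU);
#' * `spot_reproducibility()`: the corrected (N - 1 denominator) sample
#'   standard deviation of the logged values, `sigma_s = sd(L_i)` — the
#'   day-to-day reproducibility;
#' * `spot_distance_accuracy()`: the mean over fractions of the per-fraction
#'   2D Euclidean distance `d_i = sqrt(dx_i^2 + dy_i^2)` between logged and
#'   planned position. Because distances are unsigned this is always at least
#'   `sqrt(mu_x^2 + mu_y^2)`.
#'
#' The study design calls for at least 15 fractions; fewer (but >= 2) are
#' accepted with a warning.
#'
#' @param values_logged Logged values of one spot parameter, one per fraction.
#' @param value_planned The planned value.
#' @return A scalar in the units of the input.
#' @export
#' @examples
#' spot_accuracy(c(1.0, 1.2, 0.8), 0.9)   # 0.1
#' spot_reproducibility(c(1, 2, 3))       # 1
#' spot_distance_accuracy(c(3, -3), c(4, 4), 0, 0)  # 5
spot_accuracy <- function(values_logged, value_planned) {
  n <- length(values_logged)
  if (n < 2) stop_lfqa("need >= 2 fractions", "lfqa_invalid_data")
  warn_few_fractions(n)
  mean(values_logged - value_planned)
}

#' @rdname spot_accuracy
#' @export
spot_reproducibility <- function(values_logged) {
  n <- length(values_logged)
  if (n < 2) stop_lfqa("need >= 2 fractions", "lfqa_invalid_data")
  warn_few_fractions(n)
  sd(values_logged)
}

#' @rdname spot_accuracy
#' @param x_logged,y_logged Logged positions per fraction (mm).
#' @param x_plan,y_plan Planned position (mm).
#' @export
spot_distance_accuracy <- function(x_logged, y_logged, x_plan, y_plan) {
  if (length(x_logged) != length(y_logged) || length(x_logged) < 1) {
    stop_lfqa("x and y must have equal length >= 1", "lfqa_invalid_data")
  }
  mean(hypot(x_logged - x_plan, y_logged - y_plan))
}

warn_few_fractions <- function(n) {
  if (n < 15) {
    warn(sprintf("only %d fractions; the method is designed for N >= 15", n),
         class = "lfqa_few_fractions")
  }
}

#' Per-spot statistics over a course of fractions
#'
#' Joins every (non-aborted) fraction log to the plan by spot key and
#' computes, per spot: accuracy `mu_x`, `mu_y`, `mu_mu`, reproducibility
#' `sigma_x`, `sigma_y`, `sigma_mu`, and the mean 2D distance to the planned
#' position. Aborted fractions are dropped entirely (their partial spot lists
#' would bias per-spot sample sizes).
#'
#' @param plan An `lfqa_plan`.
#' @param fractions List of `fraction_log`s.
#' @return A tibble of class `lfqa_spot_stats`: one row per spot with the
#'   plan key columns, `gantry_angle`, `n_fractions`, and the seven
#'   statistics. Also records the mean-vector-norm variant
#'   `distance_of_means = hypot(mu_x, mu_y)` alongside the default
#'   `mean_distance`.
#' @export
spot_statistics <- function(plan, fractions) {
  usable <- purrr::keep(fractions, ~ !.x$aborted)
  if (length(usable) < 2) {
    stop_lfqa("need >= 2 non-aborted fractions", "lfqa_invalid_data")
  }
  warn_few_fractions(length(usable))
  logged <- purrr::map_dfr(usable, function(fr) {
    dplyr::mutate(fr$spots[, c(spot_key_cols, "x_mm", "y_mm", "mu")],
                  fraction_index = fr$fraction_index)
  })
  joined <- dplyr::inner_join(
    logged,
    plan[, c("plan_id", spot_key_cols, "gantry_angle", "x_mm", "y_mm", "mu")],
    by = spot_key_cols, suffix = c("_log", "_plan")
  )
  out <- joined |>
    dplyr::group_by(.data$plan_id, .data$field_id, .data$gantry_angle,
                    .data$layer_index, .data$spot_index) |>
    dplyr::summarise(
      n_fractions = dplyr::n(),
      mu_x = mean(.data$x_mm_log - .data$x_mm_plan),
      mu_y = mean(.data$y_mm_log - .data$y_mm_plan),
      mu_mu = mean(.data$mu_log - .data$mu_plan),
      sigma_x = sd(.data$x_mm_log),
      sigma_y = sd(.data$y_mm_log),
      sigma_mu = sd(.data$mu_log),
      mean_distance = mean(hypot(.data$x_mm_log - .data$x_mm_plan,
                                 .data$y_mm_log - .data$y_mm_plan)),
      .groups = "drop"
    ) |>
    dplyr::mutate(distance_of_means = hypot(.data$mu_x, .data$mu_y))
  class(out) <- c("lfqa_spot_stats", class(out))
  out
}

#' Five-number distribution summary with 1.5 IQR whiskers
#'
#' Median, quartiles (linear-interpolation convention, `quantile` type 7) and
#' whiskers at the furthest data point within 1.5 x IQR of the quartiles —
#' the box-and-whisker convention used for the violin summaries.
#'
#' @param x Numeric vector.
#' @return A one-row tibble: `median`, `q1`, `q3`, `whisker_low`,
#'   `whisker_high`, `n`.
#' @export
distribution_summary <- function(x) {
  x <- x[is.finite(x)]
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo_candidates <- x[x >= q[1] - 1.5 * iqr]
  hi_candidates <- x[x <= q[3] + 1.5 * iqr]
  tibble::tibble(
    median = q[2], q1 = q[1], q3 = q[3],
    whisker_low = min(lo_candidates),
    whisker_high = max(hi_candidates),
    n = length(x)
  )
}

#' Aggregate per-spot statistics per plan or per gantry angle
#'
#' Summarises each per-spot quantity (`mu_x`, `mu_y`, `mu_mu`, `sigma_x`,
#' `sigma_y`, `sigma_mu`, `mean_distance`) within each group: the mean, the
#' worst value (largest magnitude, sign preserved — so a summary row reading
#' `0.0 (-1.4)` means mean 0.0, worst -1.4), and the
#' [distribution_summary()]. Grouping by `gantry_angle` assigns every spot
#' its field's angle.
#'
#' @param stats An [spot_statistics()] tibble.
#' @param group_by `"plan"` or `"gantry_angle"`.
#' @return A tibble with one row per (group, quantity).
#' @export
aggregate_spot_statistics <- function(stats, group_by = c("plan", "gantry_angle")) {
  group_by <- match.arg(group_by)
  if (nrow(stats) == 0) stop_lfqa("empty statistics", "lfqa_invalid_data")
  key <- if (group_by == "plan") "plan_id" else "gantry_angle"
  quantities <- c("mu_x", "mu_y", "mu_mu", "sigma_x", "sigma_y", "sigma_mu",
                  "mean_distance")
  long <- tidyr::pivot_longer(
    stats[, c(key, quantities)],
    cols = dplyr::all_of(quantities),
    names_to = "quantity", values_to = "value"
  )
  long |>
    dplyr::group_by(.data[[key]], .data$quantity) |>
    dplyr::summarise(
      mean = mean(.data$value),
      worst = worst_value(.data$value),
      distribution_summary(.data$value),
      .groups = "drop"
    )
}

# Largest-magnitude value with its sign preserved.
worst_value <- function(x) x[which.max(abs(x))]
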