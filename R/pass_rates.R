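#' MU-weighted spot-based pass rate Lambda(D)
#'
#' The log-file pass rate of one delivered fraction: the percentage of the
#' fraction's total recorded MU carried by spots delivered strictly within
#' the tolerance distance `D` of their reference position,
#' `Lambda(D) = 100 * sum(MU_s * [d_s < D]) / sum(MU_s)`. Both the weights
#' and the distances come from the fraction's log record; ties (`d == D`)
#' fail the strict inequality.
#'
#' @param mu Recorded spot MU, one per spot.
#' @param d 2D distances to the reference positions (mm), same length.
#' @param tolerance_d Tolerance distance D (mm). Default 1 mm, the value
#'   paired with the 1%/1 mm gamma criterion.
#' @return Pass rate in percent.
#' @export
#' @examples
#' lambda_pass_rate(c(1, 2, 3), c(0.5, 1.5, 0.9), 1)  # (1 + 3) / 6 = 66.67
lambda_pass_rate <- function(mu, d, tolerance_d = 1) {
  if (length(mu) != length(d)) {
    stop_lfqa("`mu` and `d` must have equal length", "lfqa_invalid_data")
  }
  total <- sum(mu)
  if (total <= 0) stop_lfqa("zero total MU", "lfqa_invalid_data")
  if (any(d < 0)) stop_lfqa("distances must be >= 0", "lfqa_invalid_data")
  100 * sum(mu[d < tolerance_d]) / total
}

#' 2D Euclidean spot distance
#'
#' Distance between a logged spot position and its reference position (the
#' planned position, or the first fraction's logged position when that
#' serves as the reference).
#'
#' @param x_log,y_log Logged position (mm); vectorized.
#' @param x_ref,y_ref Reference position (mm).
#' @return Distance (mm).
#' @export
spot_distance <- function(x_log, y_log, x_ref, y_ref) {
  hypot(x_log - x_ref, y_log - y_ref)
}

#' Pearson product-moment correlation
#'
#' Sample Pearson correlation between two equal-length series, used to
#' correlate the spot-based pass rate Lambda(1 mm) with the gamma pass rate
#' Gamma(1%/1 mm) across the fractions of a plan. When either series has
#' zero variance the correlation is undefined and reported as missing
#' (`NA`), never as 0.
#'
#' @param series_a,series_b Numeric vectors of equal length >= 3.
#' @return Correlation coefficient, or `NA` if undefined.
#' @export
pearson <- function(series_a, series_b) {
  if (length(series_a) != length(series_b) || length(series_a) < 3) {
    stop_lfqa("need two equal-length series of >= 3 values",
              "lfqa_invalid_data")
  }
  if (sd(series_a) == 0 || sd(series_b) == 0) {
    rlang::inform("correlation undefined: a series has zero variance",
                  class = "lfqa_zero_variance")
    return(NA_real_)
  }
  cor(series_a, series_b, method = "pearson")
}

#' Per-fraction Lambda and Gamma pass-rate series for a plan
#'
#' Runs the fraction-wise pass-rate analysis of a delivered course against a
#' chosen reference:
#'
#' * `reference_kind = "original_plan"`: spot distances are measured to the
#'   planned positions and the reference dose is the planned dose;
#' * `reference_kind = "first_fraction"`: distances are measured spot-by-spot
#'   to the first delivered fraction's logged positions and the reference
#'   dose is that fraction's reconstructed dose (the pre-treatment LFQA
#'   surrogate). Fraction 1 is included and scores 100% on both metrics by
#'   construction.
#'
#' Aborted fractions are excluded. The gamma normalization is fixed once
#' from the reference dose maximum. Lambda uses each fraction's own recorded
#' MU as weights and denominator. The Pearson correlation between
#' Lambda(`tolerance_d`) and the gamma pass rate across fractions is
#' attached.
#'
#' @param plan An `lfqa_plan`.
#' @param fractions List of `fraction_log`s.
#' @param grid A [dose_grid()] defining the reconstruction geometry.
#' @param beam A [beam_model()].
#' @param criteria A [gamma_criteria()]; default 1%/1 mm.
#' @param tolerance_d Lambda tolerance distance (mm).
#' @param reference_kind `"original_plan"` or `"first_fraction"`.
#' @param phantom_entry_depth Passed to [reconstruct_dose()].
#' @return A tibble of class `lfqa_series` with columns `fraction_index`,
#'   `lambda_percent`, `gamma_percent`, and attributes `plan_id`,
#'   `reference_kind`, `tolerance_d`, `criteria` and `pearson_r`. Use
#'   [tidy()]/[glance()] to extract.
#' @export
build_series <- function(plan, fractions, grid, beam = beam_model(),
                         criteria = gamma_criteria(1, 1),
                         tolerance_d = 1,
                         reference_kind = c("original_plan", "first_fraction"),
                         phantom_entry_depth = 60) {
  reference_kind <- match.arg(reference_kind)
  usable <- purrr::keep(fractions, ~ !.x$aborted)
  if (length(usable) < 3) {
    stop_lfqa("need >= 3 non-aborted fractions", "lfqa_insufficient_data")
  }
  usable <- usable[order(purrr::map_int(usable, "fraction_index"))]

  ref_spots <- if (reference_kind == "original_plan") {
    plan[, c(spot_key_cols, "x_mm", "y_mm")]
  } else {
    usable[[1]]$spots[, c(spot_key_cols, "x_mm", "y_mm")]
  }
  ref_plan <- if (reference_kind == "original_plan") {
    plan
  } else {
    build_logfile_plan(plan, usable[[1]])
  }
  ref_dose <- reconstruct_dose(ref_plan, grid, beam,
                               phantom_entry_depth = phantom_entry_depth)
  criteria$normalization <- criteria$normalization %||% max(ref_dose$values)

  rows <- purrr::map_dfr(usable, function(fr) {
    sp <- dplyr::inner_join(fr$spots, ref_spots, by = spot_key_cols,
                            suffix = c("_log", "_ref"))
    d <- spot_distance(sp$x_mm_log, sp$y_mm_log, sp$x_mm_ref, sp$y_mm_ref)
    lam <- lambda_pass_rate(sp$mu, d, tolerance_d)
    fdose <- reconstruct_dose(build_logfile_plan(plan, fr), grid, beam,
                              phantom_entry_depth = phantom_entry_depth)
    gam <- gamma_index(ref_dose, fdose, criteria)$pass_rate
    tibble::tibble(fraction_index = fr$fraction_index,
                   lambda_percent = lam, gamma_percent = gam)
  })

  r <- if (sd(rows$lambda_percent) == 0 || sd(rows$gamma_percent) == 0) {
    NA_real_
  } else {
    cor(rows$lambda_percent, rows$gamma_percent)
  }
  new_lfqa_series(rows, plan_id = plan$plan_id[1],
                  reference_kind = reference_kind,
                  tolerance_d = tolerance_d, criteria = criteria,
                  pearson_r = r)
}

new_lfqa_series <- function(rows, plan_id, reference_kind, tolerance_d,
                            criteria, pearson_r) {
  out <- tibble::as_tibble(rows)
  attr(out, "plan_id") <- plan_id
  attr(out, "reference_kind") <- reference_kind
  attr(out, "tolerance_d") <- tolerance_d
  attr(out, "criteria") <- criteria
  attr(out, "pearson_r") <- pearson_r
  class(out) <- c("lfqa_series", class(tibble::tibble()))
  out
}

#' Tidy a pass-rate series
#'
#' @param x An `lfqa_series` from [build_series()].
#' @param ... Unused.
#' @return `tidy()`: one row per fraction with plan and reference metadata;
#'   `glance()`: a one-row summary (mean/min of both pass rates, Pearson r).
#' @export
tidy.lfqa_series <- function(x, ...) {
  tibble::tibble(
    plan_id = attr(x, "plan_id"),
    reference_kind = attr(x, "reference_kind"),
    fraction_index = x$fraction_index,
    lambda_percent = x$lambda_percent,
    gamma_percent = x$gamma_percent
  )
}

#' @rdname tidy.lfqa_series
#' @export
glance.lfqa_series <- function(x, ...) {
  tibble::tibble(
    plan_id = attr(x, "plan_id"),
    reference_kind = attr(x, "reference_kind"),
    n_fractions = nrow(x),
    mean_lambda = mean(x$lambda_percent),
    min_lambda = min(x$lambda_percent),
    mean_gamma = mean(x$gamma_percent),
    min_gamma = min(x$gamma_percent),
    pearson_r = attr(x, "pearson_r")
  )
}
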