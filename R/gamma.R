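#' Gamma analysis criteria
#'
#' Settings of the global 3D gamma index comparison: dose-difference
#' criterion as a percentage of a fixed normalization dose, distance to
#' agreement (DTA), low-dose cutoff as a fraction of the normalization,
#' sub-voxel sampling step as a fraction of the DTA, and the search radius.
#' The clinical pairs used throughout are 2%/2 mm and 1%/1 mm, both with a
#' 10% low-dose cutoff and a 10%-of-DTA interpolation step.
#'
#' @param dose_percent Dose-difference criterion (% of normalization), > 0.
#' @param dta Distance to agreement (mm), > 0.
#' @param cutoff_fraction Low-dose cutoff as a fraction of the normalization
#'   dose; reference voxels below it are not evaluated.
#' @param interp_fraction Sub-voxel sampling step as a fraction of `dta`.
#' @param normalization Fixed normalization dose. `NULL` (default) uses the
#'   maximum of the designated reference dose, held constant across all
#'   fractions of a series.
#' @param search_radius_factor Search radius in units of `dta`; beyond it the
#'   distance term alone exceeds this gamma value, which is then recorded
#'   as is.
#' @return An object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_percent, dta, cutoff_fraction = 0.10,
                           interp_fraction = 0.10, normalization = NULL,
                           search_radius_factor = 3) {
  assert_scalar_number(dose_percent, "dose_percent", 0, strict = TRUE)
  assert_scalar_number(dta, "dta", 0, strict = TRUE)
  assert_scalar_number(cutoff_fraction, "cutoff_fraction", 0)
  if (interp_fraction <= 0 || interp_fraction > 1) {
    stop_lfqa("`interp_fraction` must be in (0, 1]", "lfqa_invalid_argument")
  }
  assert_scalar_number(search_radius_factor, "search_radius_factor", 0,
                       strict = TRUE)
  if (!is.null(normalization)) {
    assert_scalar_number(normalization, "normalization", 0, strict = TRUE)
  }
  structure(
    list(dose_percent = dose_percent, dta = dta,
         cutoff_fraction = cutoff_fraction,
         interp_fraction = interp_fraction,
         normalization = normalization,
         search_radius_factor = search_radius_factor),
    class = "gamma_criteria"
  )
}

#' 3D global gamma index of an evaluation dose against a reference
#'
#' For every reference voxel at or above the low-dose cutoff, searches the
#' evaluation dose (trilinearly interpolated on a lattice of step
#' `interp_fraction * dta` within `search_radius_factor * dta`) for the
#' minimum combined dose-difference / distance-to-agreement index
#' `gamma(r) = min_e sqrt(|r - e|^2 / dta^2 + (D_e - D_r)^2 / dD^2)` with
#' `dD = dose_percent/100 * normalization`. A voxel passes when
#' `gamma <= 1`; the pass rate is the passing percentage of evaluated
#' voxels. Offsets are searched in order of increasing distance with an
#' exact early exit, so results are identical to a dense search.
#'
#' @param reference,evaluation `dose_grid`s on a common frame (origins and
#'   spacings may differ; the evaluation is interpolated).
#' @param criteria A [gamma_criteria()]. A `NULL` normalization is resolved
#'   to `max(reference$values)`.
#' @param keep_gamma_map Retain the per-voxel gamma map in the result.
#' @return An object of class `gamma_result`: `pass_rate` (%),
#'   `n_evaluated`, `n_pass`, `n_no_sample` (evaluated voxels with no
#'   evaluation-dose sample point in reach), `normalization`, and (optional)
#'   `gamma_map` as a `dose_grid`-shaped array with `NA` below the cutoff.
#' @export
gamma_index <- function(reference, evaluation, criteria,
                        keep_gamma_map = FALSE) {
  norm <- criteria$normalization %||% max(reference$values)
  if (norm <= 0) {
    stop_lfqa("gamma normalization must be positive", "lfqa_invalid_argument")
  }
  res <- cpp_gamma(
    as.numeric(reference$values), reference$shape, reference$origin,
    reference$spacing,
    as.numeric(evaluation$values), evaluation$shape, evaluation$origin,
    evaluation$spacing,
    criteria$dose_percent, criteria$dta, criteria$cutoff_fraction,
    criteria$interp_fraction, norm, criteria$search_radius_factor,
    TRUE
  )
  if (res$n_evaluated == 0) {
    stop_lfqa("no reference voxel reaches the low-dose cutoff",
              "lfqa_invalid_data")
  }
  if (res$n_no_sample > 0) {
    warn(sprintf(
      "%d evaluated voxel(s) had no evaluation-dose sample point in reach",
      res$n_no_sample), class = "lfqa_boundary_warning")
  }
  structure(
    list(
      pass_rate = 100 * res$n_pass / res$n_evaluated,
      n_evaluated = res$n_evaluated,
      n_pass = res$n_pass,
      n_no_sample = res$n_no_sample,
      normalization = norm,
      gamma_map = if (keep_gamma_map) array(res$gamma, dim = reference$shape)
    ),
    class = "gamma_result"
  )
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> pass rate %.2f%% (%d of %d voxels evaluated)\n",
              x$pass_rate, as.integer(x$n_pass), as.integer(x$n_evaluated)))
  invisible(x)
}

#' Gamma pass rates of a series of fraction doses
#'
#' Compares each reconstructed fraction dose against the same reference with
#' a normalization fixed once from the reference maximum (or the criteria's
#' explicit normalization), as required when tracking pass rates across the
#' fractions of a course.
#'
#' @param reference A `dose_grid`.
#' @param fraction_doses List of `dose_grid`s, one per fraction.
#' @param criteria A [gamma_criteria()].
#' @return Numeric vector of pass rates (%), one per fraction.
#' @export
gamma_series <- function(reference, fraction_doses, criteria) {
  if (length(fraction_doses) == 0) {
    stop_lfqa("empty fraction dose list", "lfqa_invalid_argument")
  }
  norm <- criteria$normalization %||% max(reference$values)
  criteria$normalization <- norm
  purrr::map_dbl(fraction_doses,
                 ~ gamma_index(reference, .x, criteria)$pass_rate)
}
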