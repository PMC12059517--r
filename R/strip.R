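#' Strip positions of the position-monitoring ionization chamber
#'
#' Strip centers for one axis of the strip-segmented IC, centered on the beam
#' axis at the IC plane.
#'
#' @param geometry A [machine_geometry()].
#' @return Numeric vector of strip center positions (mm, IC plane).
#' @export
strip_positions <- function(geometry) {
  (seq_len(geometry$n_strips) - (geometry$n_strips + 1) / 2) * geometry$strip_pitch
}

#' Synthesize a strip-chamber charge profile for one spot
#'
#' Distributes a spot's accumulated charge over the IC strips: each strip
#' collects the Gaussian beam mass over its pitch interval, plus optional
#' additive readout noise. With zero noise the strip charges sum to
#' `total_charge` exactly (up to the Gaussian mass outside the strip
#' coverage).
#'
#' @param x_true_ic True beam centroid at the IC plane (mm).
#' @param beam_sigma_ic Beam sigma at the IC plane (mm), > 0.
#' @param total_charge Accumulated charge of the spot.
#' @param geometry A [machine_geometry()].
#' @param noise_sd Additive Gaussian noise SD per strip (charge units).
#' @return Numeric vector of per-strip charges (length `geometry$n_strips`).
#' @export
synthesize_strip_profile <- function(x_true_ic, beam_sigma_ic, total_charge,
                                     geometry = machine_geometry(),
                                     noise_sd = 0) {
  assert_scalar_number(beam_sigma_ic, "beam_sigma_ic", 0, strict = TRUE)
  pos <- strip_positions(geometry)
  half <- geometry$strip_pitch / 2
  lo <- min(pos) - half
  hi <- max(pos) + half
  if (x_true_ic - 3 * beam_sigma_ic < lo || x_true_ic + 3 * beam_sigma_ic > hi) {
    stop_lfqa("beam centroid +/- 3 sigma falls outside the strip coverage",
              "lfqa_coverage_error")
  }
  mass <- stats::pnorm(pos + half, x_true_ic, beam_sigma_ic) -
    stats::pnorm(pos - half, x_true_ic, beam_sigma_ic)
  charges <- total_charge * mass
  if (noise_sd > 0) charges <- charges + rnorm(length(charges), 0, noise_sd)
  charges
}

#' Fit the beam centroid from a strip charge profile
#'
#' Least-squares fit of a Gaussian curve (amplitude, center, width) to the
#' per-strip charges, initialized from the charge-weighted mean and SD.
#' Returns the fitted center with sub-strip-pitch resolution; this is the
#' micrometer-level spot position determination of the strip chambers.
#'
#' @param strip_charges Per-strip charges.
#' @param strip_positions Strip center positions (mm), same length.
#' @return Fitted centroid (mm, IC plane).
#' @export
fit_strip_centroid <- function(strip_charges, strip_positions) {
  if (length(strip_charges) != length(strip_positions) ||
      length(strip_charges) < 5) {
    stop_lfqa("need >= 5 strips with matching positions", "lfqa_invalid_data")
  }
  if (sum(strip_charges) <= 0) {
    stop_lfqa("non-positive total charge", "lfqa_invalid_data")
  }
  peak <- which.max(strip_charges)
  if (peak == 1L || peak == length(strip_charges)) {
    stop_lfqa("charge peak on a boundary strip: beam outside strip coverage",
              "lfqa_coverage_error")
  }
  w <- pmax(strip_charges, 0)
  c0 <- sum(w * strip_positions) / sum(w)
  s0 <- sqrt(sum(w * (strip_positions - c0)^2) / sum(w))
  if (!is.finite(s0) || s0 <= 0) s0 <- diff(range(strip_positions)) / 10
  df <- data.frame(q = strip_charges, x = strip_positions)
  fit <- minpack.lm::nlsLM(
    q ~ a * exp(-(x - c)^2 / (2 * s^2)),
    data = df,
    start = list(a = max(strip_charges), c = c0, s = s0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  unname(stats::coef(fit)[["c"]])
}

#' Project an IC-plane coordinate into the isocenter plane
#'
#' Similar triangles (intercept theorem) from the per-axis virtual scanning
#' source through the IC plane to the isocenter plane:
#' `x_iso = x_ic * sad / (sad - z_ic)`.
#'
#' @param x_ic Coordinate measured at the IC plane (mm); vectorized.
#' @param axis `"x"` or `"y"` (the two axes have different virtual SADs).
#' @param geometry A [machine_geometry()].
#' @return Isocenter-plane coordinate (mm).
#' @export
project_to_isocenter <- function(x_ic, axis = c("x", "y"),
                                 geometry = machine_geometry()) {
  axis <- match.arg(axis)
  sad <- if (axis == "x") geometry$sad_x else geometry$sad_y
  if (sad <= geometry$z_ic) {
    stop_lfqa("SAD must exceed the IC plane distance", "lfqa_invalid_geometry")
  }
  x_ic * sad / (sad - geometry$z_ic)
}

# Inverse projection used by the log writer.
project_to_ic <- function(x_iso, axis = c("x", "y"),
                          geometry = machine_geometry()) {
  axis <- match.arg(axis)
  sad <- if (axis == "x") geometry$sad_x else geometry$sad_y
  x_iso * (sad - geometry$z_ic) / sad
}

#' Convert accumulated chamber charge to MU
#'
#' Applies the machine-specific calibration factor and the conventional air
#' density correction for the ambient conditions at delivery time:
#' `MU = charge * k * (p_ref / p) * (T / T_ref)`.
#'
#' @param charge Accumulated charge (vectorized).
#' @param calibration_factor MU per unit charge, > 0.
#' @param conditions An [ambient_conditions()].
#' @param geometry A [machine_geometry()] carrying the reference conditions.
#' @return Monitor units.
#' @export
charge_to_mu <- function(charge, calibration_factor,
                         conditions = ambient_conditions(),
                         geometry = machine_geometry()) {
  assert_scalar_number(calibration_factor, "calibration_factor", 0,
                       strict = TRUE)
  if (conditions$pressure <= 0 || conditions$temperature <= 0) {
    stop_lfqa("ambient pressure and temperature must be positive",
              "lfqa_invalid_data")
  }
  charge * calibration_factor *
    (geometry$ref_pressure / conditions$pressure) *
    (conditions$temperature / geometry$ref_temperature)
}

mu_to_charge <- function(mu, calibration_factor,
                         conditions = ambient_conditions(),
                         geometry = machine_geometry()) {
  mu / (calibration_factor *
          (geometry$ref_pressure / conditions$pressure) *
          (conditions$temperature / geometry$ref_temperature))
}
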