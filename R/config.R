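#' Machine geometry for the scanning nozzle
#'
#' Describes the beam-monitoring geometry used to turn ionization-chamber (IC)
#' plane readings into isocenter-plane spot coordinates and MU: the per-axis
#' virtual source-to-axis distances (scanning magnets sit at different
#' distances for the fast x and slow y axis), the position of the strip IC
#' plane upstream of the isocenter, the strip grid, and the charge-to-MU
#' calibration with its reference ambient conditions.
#'
#' @param sad_x,sad_y Virtual source-to-axis distance per scanning axis (mm).
#' @param z_ic Distance of the strip IC plane upstream of the isocenter (mm);
#'   must be smaller than both SADs.
#' @param strip_pitch Strip pitch of the position ICs (mm).
#' @param n_strips Number of strips per axis (>= 5).
#' @param calibration_factor Machine-specific conversion factor, MU per unit
#'   of accumulated chamber charge.
#' @param ref_pressure,ref_temperature Reference ambient conditions of the
#'   calibration (hPa, K) for the air density correction.
#'
#' @return An object of class `machine_geometry`.
#' @export
machine_geometry <- function(sad_x = 2300, sad_y = 1800, z_ic = 450,
                             strip_pitch = 2, n_strips = 160,
                             calibration_factor = 0.2,
                             ref_pressure = 1013.25, ref_temperature = 293.15) {
  assert_scalar_number(sad_x, "sad_x", 0, strict = TRUE)
  assert_scalar_number(sad_y, "sad_y", 0, strict = TRUE)
  assert_scalar_number(z_ic, "z_ic", 0, strict = TRUE)
  if (sad_x <= z_ic || sad_y <= z_ic) {
    stop_lfqa("SADs must exceed the IC plane distance `z_ic`",
              "lfqa_invalid_geometry")
  }
  if (n_strips < 5) stop_lfqa("`n_strips` must be >= 5", "lfqa_invalid_argument")
  assert_scalar_number(strip_pitch, "strip_pitch", 0, strict = TRUE)
  assert_scalar_number(calibration_factor, "calibration_factor", 0, strict = TRUE)
  assert_scalar_number(ref_pressure, "ref_pressure", 0, strict = TRUE)
  assert_scalar_number(ref_temperature, "ref_temperature", 0, strict = TRUE)
  structure(
    list(
      sad_x = sad_x, sad_y = sad_y, z_ic = z_ic,
      strip_pitch = strip_pitch, n_strips = as.integer(n_strips),
      calibration_factor = calibration_factor,
      ref_pressure = ref_pressure, ref_temperature = ref_temperature
    ),
    class = "machine_geometry"
  )
}

#' Ambient conditions at delivery time
#'
#' Pressure and temperature used for the conventional air density correction
#' when converting accumulated chamber charge to MU.
#'
#' @param pressure Air pressure (hPa), > 0.
#' @param temperature Air temperature (K), > 0.
#' @return An object of class `ambient_conditions`.
#' @export
ambient_conditions <- function(pressure = 1013.25, temperature = 293.15) {
  assert_scalar_number(pressure, "pressure", 0, strict = TRUE)
  assert_scalar_number(temperature, "temperature", 0, strict = TRUE)
  structure(list(pressure = pressure, temperature = temperature),
            class = "ambient_conditions")
}

#' Machine error model for the delivery simulator
#'
#' Configures the systematic and random deviations the simulator injects into
#' every delivered fraction, emulating the error phenomenology of a scanning
#' proton gantry:
#'
#' * a gantry-angle-dependent systematic x offset (worst for horizontal beams,
#'   negative near 90 deg and positive near 270 deg with the default sine
#'   profile), attributed to angle-dependent beam transport;
#' * reproducible per-scan-row y offsets from scanning magnet calibration;
#' * a random per-layer, per-fraction y shift from degraded layer tuning;
#' * per-spot, per-fraction, per-axis Gaussian position noise, inflated by
#'   `edge_highmu_noise_multiplier` for heavy spots (`mu_plan >=
#'   highmu_threshold`) sitting on the lateral field edge of their layer;
#' * MU bias and noise; and
#' * the timing model: drill time proportional to MU, Gaussian spot-switch and
#'   energy-switch intervals, and random machine interlocks.
#'
#' @param x_offset_amplitude Amplitude A of the systematic x offset (mm).
#' @param x_offset_angle_profile Either the string `"sine"` (offset
#'   `-A * sin(gantry_angle)`, giving a negative offset at 90 deg and a
#'   positive one at 270 deg) or a function `f(angle_deg)` returning the
#'   offset in units of `x_offset_amplitude`.
#' @param y_row_offset Scale of the reproducible per-scan-row y offset (mm);
#'   each row of each layer receives a fixed offset drawn uniformly from
#'   `[-y_row_offset, y_row_offset]`, constant across fractions.
#' @param layer_tune_shift_sd SD of the per-layer, per-fraction random y shift
#'   applied to all spots of the layer (mm).
#' @param position_noise_sd Per-spot, per-fraction, per-axis Gaussian position
#'   noise SD (mm).
#' @param edge_highmu_noise_multiplier Multiplier (>= 1) applied to
#'   `position_noise_sd` for high-MU spots on the lateral field edge.
#' @param highmu_threshold MU above which a spot counts as high-MU.
#' @param mu_noise_sd Per-spot MU noise SD (MU).
#' @param mu_bias Systematic MU offset (MU).
#' @param drill_time_per_mu Beam-on (drill) time per MU (ms/MU).
#' @param spot_switch_time_ms,spot_switch_time_sd_ms Mean and SD of the
#'   within-layer spot switching interval (ms).
#' @param energy_switch_time_s,energy_switch_time_sd_s Mean and SD of the
#'   between-layer energy switching interval (s).
#' @param interlock_probability_per_field Probability that a field delivery is
#'   interrupted by a machine interlock.
#' @param interlock_duration_s,interlock_duration_sd_s Mean and SD of the
#'   interlock duration (s).
#' @param rng_seed Integer seed from which all per-(fraction, field, layer)
#'   substreams are derived.
#'
#' @return An object of class `error_model`.
#' @export
error_model <- function(x_offset_amplitude = 0,
                        x_offset_angle_profile = "sine",
                        y_row_offset = 0,
                        layer_tune_shift_sd = 0,
                        position_noise_sd = 0,
                        edge_highmu_noise_multiplier = 1,
                        highmu_threshold = 0.05,
                        mu_noise_sd = 0,
                        mu_bias = 0,
                        drill_time_per_mu = 100,
                        spot_switch_time_ms = 2,
                        spot_switch_time_sd_ms = 0,
                        energy_switch_time_s = 1,
                        energy_switch_time_sd_s = 0,
                        interlock_probability_per_field = 0,
                        interlock_duration_s = 30,
                        interlock_duration_sd_s = 0,
                        rng_seed = 1L) {
  for (nm in c("y_row_offset", "layer_tune_shift_sd", "position_noise_sd",
               "mu_noise_sd", "drill_time_per_mu", "spot_switch_time_ms",
               "spot_switch_time_sd_ms", "energy_switch_time_s",
               "energy_switch_time_sd_s", "interlock_duration_s",
               "interlock_duration_sd_s")) {
    assert_scalar_number(get(nm), nm, 0)
  }
  if (edge_highmu_noise_multiplier < 1) {
    stop_lfqa("`edge_highmu_noise_multiplier` must be >= 1",
              "lfqa_invalid_argument")
  }
  if (interlock_probability_per_field < 0 || interlock_probability_per_field > 1) {
    stop_lfqa("`interlock_probability_per_field` must be in [0, 1]",
              "lfqa_invalid_argument")
  }
  profile_fun <-
    if (is.function(x_offset_angle_profile)) {
      x_offset_angle_profile
    } else if (identical(x_offset_angle_profile, "sine")) {
      function(angle_deg) -sin(angle_deg * pi / 180)
    } else {
      stop_lfqa("`x_offset_angle_profile` must be \"sine\" or a function",
                "lfqa_invalid_argument")
    }
  structure(
    list(
      x_offset_amplitude = x_offset_amplitude,
      x_offset_angle_profile = profile_fun,
      y_row_offset = y_row_offset,
      layer_tune_shift_sd = layer_tune_shift_sd,
      position_noise_sd = position_noise_sd,
      edge_highmu_noise_multiplier = edge_highmu_noise_multiplier,
      highmu_threshold = highmu_threshold,
      mu_noise_sd = mu_noise_sd,
      mu_bias = mu_bias,
      drill_time_per_mu = drill_time_per_mu,
      spot_switch_time_ms = spot_switch_time_ms,
      spot_switch_time_sd_ms = spot_switch_time_sd_ms,
      energy_switch_time_s = energy_switch_time_s,
      energy_switch_time_sd_s = energy_switch_time_sd_s,
      interlock_probability_per_field = interlock_probability_per_field,
      interlock_duration_s = interlock_duration_s,
      interlock_duration_sd_s = interlock_duration_sd_s,
      rng_seed = as.integer(rng_seed)
    ),
    class = "error_model"
  )
}

#' Analytic pencil-beam model for dose reconstruction
#'
#' Parameterizes the stand-in dose engine: a Bragg-Kleeman style range-energy
#' relation `R(E) = alpha * E^p` (mm when `alpha` is given in mm/MeV^p), a
#' normalized depth-dose curve with a quadratic build-up plateau and a
#' Gaussian-shaped Bragg peak of width `bragg_width`, and a lateral Gaussian
#' whose sigma grows linearly with depth. The depth-dose is normalized to unit
#' area so that the integral dose of a spot equals its MU (up to kernel mass
#' escaping the grid); only the sensitivity of dose to spot position and MU
#' perturbations matters here, not absolute dosimetry.
#'
#' @param range_alpha Range coefficient alpha (mm/MeV^p). The default with
#'   `range_p = 1.77` reproduces the familiar ~76 mm range of 100 MeV protons
#'   in water.
#' @param range_p Range exponent p (dimensionless).
#' @param bragg_width SD of the Gaussian Bragg peak (mm).
#' @param sigma0 Lateral beam sigma at zero depth (mm).
#' @param sigma_growth Lateral sigma growth per mm depth (mm/mm).
#' @return An object of class `beam_model`.
#' @export
beam_model <- function(range_alpha = 0.022, range_p = 1.77,
                       bragg_width = 5, sigma0 = 4, sigma_growth = 0.02) {
  assert_scalar_number(range_alpha, "range_alpha", 0, strict = TRUE)
  assert_scalar_number(range_p, "range_p", 0, strict = TRUE)
  assert_scalar_number(bragg_width, "bragg_width", 0, strict = TRUE)
  assert_scalar_number(sigma0, "sigma0", 0, strict = TRUE)
  assert_scalar_number(sigma_growth, "sigma_growth", 0)
  structure(
    list(range_alpha = range_alpha, range_p = range_p,
         bragg_width = bragg_width, sigma0 = sigma0,
         sigma_growth = sigma_growth),
    class = "beam_model"
  )
}

#' Proton range in water for a beam energy
#'
#' @param energy_mev Beam energy (MeV).
#' @param beam A [beam_model()].
#' @return Range in mm.
#' @export
beam_range <- function(energy_mev, beam = beam_model()) {
  beam$range_alpha * energy_mev^beam$range_p
}
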