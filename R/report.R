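#' Run the full log-file QA pipeline from a config file
#'
#' Orchestrates every stage for one synthetic plan: simulate the course,
#' write and re-read the record/events log files, compute per-spot
#' statistics and their aggregation, reconstruct planned and per-fraction
#' doses, compute the Lambda/Gamma pass-rate series against the configured
#' reference(s), decompose delivery timing, and emit a per-plan report row
#' plus machine-readable summaries under `outdir`:
#'
#' * `logs/` — record CSV and events JSON-lines files per fraction/field
#' * `plan.json` — the generated plan
#' * `spot_statistics.csv`, `spot_summary.csv`
#' * `series_<reference>.csv`
#' * `timing.csv`, `timing_summary.csv`
#' * `report.csv`, `report.json` — the formatted per-plan report
#' * `manifest.json` — config hash, seed and package version
#'
#' See `lfqa_demo_config()` for the schema; unknown keys are rejected with
#' their full path.
#'
#' @param config_path Path to a YAML or JSON config file.
#' @param outdir Output directory (created).
#' @param seed Optional override of the simulation seed.
#' @return Invisibly, a list with the report tibble and the stage objects
#'   (`plan`, `fractions`, `stats`, `series`, `timing`).
#' @export
run_pipeline <- function(config_path, outdir, seed = NULL) {
  cfg <- read_pipeline_config(config_path)
  if (!is.null(seed)) cfg$simulation$seed <- seed
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  message("stage: plan generation")
  pc <- cfg$plan
  plan <- generate_plan(
    n_fields = pc$n_fields, gantry_angles = unlist(pc$gantry_angles),
    layers_per_field = pc$layers_per_field,
    spots_per_layer = pc$spots_per_layer,
    target_radius = pc$target_radius_mm,
    rng_seed = cfg$simulation$seed,
    plan_id = pc$plan_id %||% "plan",
    energy_min = pc$energy_min_mev %||% 90,
    energy_max = pc$energy_max_mev %||% 110
  )
  write_plan_json(plan, file.path(outdir, "plan.json"))

  geometry <- do.call(machine_geometry, cfg$geometry %||% list())
  errors <- do.call(error_model,
                    c(cfg$errors %||% list(),
                      list(rng_seed = cfg$simulation$seed)))

  message("stage: delivery simulation + log file round trip")
  logdir <- file.path(outdir, "logs")
  fractions <- purrr::map(seq_len(cfg$simulation$n_fractions), function(i) {
    fr <- simulate_fraction(plan, geometry, errors, fraction_index = i)
    paths <- write_fraction_log(fr, plan, geometry,
                                dir = file.path(logdir, sprintf("f%03d", i)))
    read_fraction(paths$record_paths, paths$events_paths, plan, geometry,
                  fraction_index = i)
  })

  message("stage: spot statistics")
  stats <- suppressWarnings(spot_statistics(plan, fractions))
  write_csv_c17(stats, file.path(outdir, "spot_statistics.csv"))
  summary_tbl <- aggregate_spot_statistics(stats, "plan")
  write_csv_c17(summary_tbl, file.path(outdir, "spot_summary.csv"))

  message("stage: dose reconstruction + pass-rate series")
  dc <- cfg$dose %||% list()
  grid <- dose_grid(shape = unlist(dc$grid_shape %||% c(40, 40, 40)),
                    spacing = dc$grid_spacing_mm %||% 3)
  beam <- do.call(beam_model, dc$beam %||% list())
  gc_cfg <- cfg$gamma %||% list()
  criteria <- gamma_criteria(
    dose_percent = gc_cfg$dose_percent %||% 1,
    dta = gc_cfg$dta_mm %||% 1,
    cutoff_fraction = gc_cfg$cutoff_fraction %||% 0.10,
    interp_fraction = gc_cfg$interp_fraction %||% 0.10,
    search_radius_factor = gc_cfg$search_radius_factor %||% 3
  )
  refs <- switch(cfg$passrates$reference %||% "original_plan",
                 both = c("original_plan", "first_fraction"),
                 cfg$passrates$reference %||% "original_plan")
  series <- lapply(refs, function(rk) {
    s <- build_series(plan, fractions, grid, beam, criteria,
                      tolerance_d = cfg$passrates$tolerance_mm %||% 1,
                      reference_kind = rk,
                      phantom_entry_depth = dc$phantom_entry_depth_mm %||% 60)
    write_csv_c17(tidy(s), file.path(outdir, sprintf("series_%s.csv", rk)))
    s
  })
  names(series) <- refs

  message("stage: timing analysis")
  timing <- purrr::map_dfr(purrr::keep(fractions, ~ !.x$aborted),
                           decompose_timing)
  write_csv_c17(timing, file.path(outdir, "timing.csv"))
  tsum <- timing_summary(timing)
  write_csv_c17(tsum, file.path(outdir, "timing_summary.csv"))

  message("stage: report")
  report <- plan_report(plan$plan_id[1], summary_tbl, series[[1]], tsum)
  rendered <- render_report(report)
  write_csv_c17(rendered, file.path(outdir, "report.csv"))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  jsonlite::write_json(
    list(config_md5 = unname(tools::md5sum(config_path)),
         seed = cfg$simulation$seed,
         package_version = as.character(utils::packageVersion("lfqa"))),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE
  )
  invisible(list(report = report, rendered = rendered, plan = plan,
                 fractions = fractions, stats = stats, series = series,
                 timing = timing))
}

write_csv_c17 <- function(df, path) {
  utils::write.csv(format_numeric_df(as.data.frame(df)), path,
                   row.names = FALSE, quote = FALSE)
}

# Assemble the per-plan report row from the stage outputs.
plan_report <- function(plan_id, summary_tbl, series, tsum) {
  g <- function(q, col) summary_tbl[[col]][summary_tbl$quantity == q]
  sg <- glance(series)
  plan_row <- tsum[tsum$level == "plan", ]
  tibble::tibble(
    plan_id = plan_id,
    mean_mu_x = g("mu_x", "mean"), worst_mu_x = g("mu_x", "worst"),
    mean_mu_y = g("mu_y", "mean"), worst_mu_y = g("mu_y", "worst"),
    mean_sigma_x = g("sigma_x", "mean"), worst_sigma_x = g("sigma_x", "worst"),
    mean_sigma_y = g("sigma_y", "mean"), worst_sigma_y = g("sigma_y", "worst"),
    mean_gamma = sg$mean_gamma, min_gamma = sg$min_gamma,
    mean_lambda = sg$mean_lambda, min_lambda = sg$min_lambda,
    pearson_r = sg$pearson_r,
    mean_delivery_time = plan_row$mean_delivery_time,
    sd_delivery_time = plan_row$two_sigma / 2
  )
}

#' Render per-plan reports with fixed formatting
#'
#' Formats one or more per-plan report rows into the summary-table layout:
#' `mean (worst)` position accuracy and reproducibility per axis,
#' `mean (min)` gamma and Lambda pass rates, the Pearson correlation and
#' `mean (sd)` delivery time. Numeric formatting is fixed — positions to
#' 1 decimal (mm), pass rates to 1 decimal (%), correlations to 2 decimals,
#' times to 2 decimals (s) — and an undefined correlation renders as `"NA"`.
#'
#' @param reports Tibble of report rows (as produced inside
#'   [run_pipeline()]).
#' @return A tibble of formatted character columns, one row per plan.
#' @export
render_report <- function(reports) {
  if (nrow(reports) == 0) stop_lfqa("no reports", "lfqa_invalid_data")
  pair <- function(a, b, digits) {
    sprintf("%.*f (%.*f)", digits, a, digits, b)
  }
  tibble::tibble(
    plan_id = reports$plan_id,
    accuracy_x_mm = pair(reports$mean_mu_x, reports$worst_mu_x, 1),
    accuracy_y_mm = pair(reports$mean_mu_y, reports$worst_mu_y, 1),
    reproducibility_x_mm = pair(reports$mean_sigma_x, reports$worst_sigma_x, 1),
    reproducibility_y_mm = pair(reports$mean_sigma_y, reports$worst_sigma_y, 1),
    gamma_percent = pair(reports$mean_gamma, reports$min_gamma, 1),
    lambda_percent = pair(reports$mean_lambda, reports$min_lambda, 1),
    pearson_r = ifelse(is.na(reports$pearson_r), "NA",
                       sprintf("%.2f", reports$pearson_r)),
    delivery_time_s = pair(reports$mean_delivery_time,
                           reports$sd_delivery_time, 2)
  )
}

#' Demo pipeline configuration
#'
#' Writes (or returns) a small, seeded two-field configuration exercising
#' every pipeline stage in seconds; also documents the config schema.
#'
#' @param path Optional path to write the YAML config to.
#' @return The config list (invisibly if written).
#' @export
lfqa_demo_config <- function(path = NULL) {
  cfg <- list(
    plan = list(plan_id = "demo", n_fields = 2,
                gantry_angles = c(90, 270), layers_per_field = 3,
                spots_per_layer = 50, target_radius_mm = 40),
    simulation = list(n_fractions = 5, seed = 20L),
    errors = list(x_offset_amplitude = 0.4, y_row_offset = 0.3,
                  position_noise_sd = 0.15, mu_noise_sd = 5e-4),
    dose = list(grid_shape = c(40, 40, 40), grid_spacing_mm = 3,
                phantom_entry_depth_mm = 60),
    gamma = list(dose_percent = 1, dta_mm = 1),
    passrates = list(tolerance_mm = 1, reference = "original_plan")
  )
  if (!is.null(path)) {
    yaml::write_yaml(cfg, path)
    return(invisible(cfg))
  }
  cfg
}

pipeline_schema <- list(
  plan = c("plan_id", "n_fields", "gantry_angles", "layers_per_field",
           "spots_per_layer", "target_radius_mm", "energy_min_mev",
           "energy_max_mev"),
  simulation = c("n_fractions", "seed"),
  geometry = c("sad_x", "sad_y", "z_ic", "strip_pitch", "n_strips",
               "calibration_factor", "ref_pressure", "ref_temperature"),
  errors = c("x_offset_amplitude", "y_row_offset", "layer_tune_shift_sd",
             "position_noise_sd", "edge_highmu_noise_multiplier",
             "highmu_threshold", "mu_noise_sd", "mu_bias",
             "drill_time_per_mu", "spot_switch_time_ms",
             "spot_switch_time_sd_ms", "energy_switch_time_s",
             "energy_switch_time_sd_s", "interlock_probability_per_field",
             "interlock_duration_s", "interlock_duration_sd_s"),
  dose = c("grid_shape", "grid_spacing_mm", "phantom_entry_depth_mm", "beam"),
  gamma = c("dose_percent", "dta_mm", "cutoff_fraction", "interp_fraction",
            "search_radius_factor"),
  passrates = c("tolerance_mm", "reference")
)

read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  bad_top <- setdiff(names(cfg), names(pipeline_schema))
  if (length(bad_top) > 0) {
    stop_lfqa(sprintf("unknown config key: `%s`", bad_top[1]),
              "lfqa_config_error")
  }
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), pipeline_schema[[sec]])
    if (length(bad) > 0) {
      stop_lfqa(sprintf("unknown config key: `%s.%s`", sec, bad[1]),
                "lfqa_config_error")
    }
  }
  if (is.null(cfg$plan) || is.null(cfg$simulation)) {
    stop_lfqa("config must contain `plan` and `simulation` sections",
              "lfqa_config_error")
  }
  beam_keys <- setdiff(names(cfg$dose$beam),
                       c("range_alpha", "range_p", "bragg_width", "sigma0",
                         "sigma_growth"))
  if (length(beam_keys) > 0) {
    stop_lfqa(sprintf("unknown config key: `dose.beam.%s`", beam_keys[1]),
              "lfqa_config_error")
  }
  invisible(cfg)
}
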