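#' Write a fraction's record and events log files
#'
#' One record CSV and one events JSON-lines file per field. The record dialect
#' carries IC-plane positions and accumulated charge (the machine-level
#' quantities); header lines prefixed `#` carry `field_id`, `gantry_angle`,
#' `pressure_hpa`, `temperature_k` and `calibration_factor`, followed by the
#' columns
#' `layer_index,energy_mev,spot_index,x_ic_mm,y_ic_mm,charge,t_start_us,t_end_us`.
#' Isocenter positions are back-projected to the IC plane per axis and MU is
#' converted to charge with the calibration factor and air density
#' correction, so [read_fraction()] inverts the writer exactly (up to written
#' decimal precision). Events are one JSON object per line with fields
#' `t_us`, `kind`, `payload`.
#'
#' @param fraction A `fraction_log` from [simulate_fraction()].
#' @param plan The `lfqa_plan` the fraction was delivered from (provides
#'   gantry angles and layer energies).
#' @param geometry A [machine_geometry()].
#' @param dir Output directory (created if missing).
#' @param conditions [ambient_conditions()] at delivery time.
#' @return Invisibly, a list with character vectors `record_paths` and
#'   `events_paths`.
#' @export
write_fraction_log <- function(fraction, plan, geometry = machine_geometry(),
                               dir = ".", conditions = ambient_conditions()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  field_ids <- unique(fraction$spots$field_id)
  energies <- dplyr::distinct(plan, .data$field_id, .data$layer_index,
                              .data$energy_mev)
  angles <- dplyr::distinct(plan, .data$field_id, .data$gantry_angle)
  record_paths <- character(0)
  events_paths <- character(0)
  for (fid in field_ids) {
    sp <- dplyr::inner_join(
      fraction$spots[fraction$spots$field_id == fid, ],
      energies[energies$field_id == fid, c("layer_index", "energy_mev")],
      by = "layer_index"
    )
    angle <- angles$gantry_angle[angles$field_id == fid]
    rec <- data.frame(
      layer_index = sp$layer_index,
      energy_mev = sp$energy_mev,
      spot_index = sp$spot_index,
      x_ic_mm = project_to_ic(sp$x_mm, "x", geometry),
      y_ic_mm = project_to_ic(sp$y_mm, "y", geometry),
      charge = mu_to_charge(sp$mu, geometry$calibration_factor, conditions,
                            geometry),
      t_start_us = sp$t_start_us,
      t_end_us = sp$t_end_us
    )
    rpath <- file.path(dir, sprintf("record_f%03d_%s.csv",
                                    fraction$fraction_index, fid))
    header <- c(
      sprintf("# field_id=%s", fid),
      sprintf("# gantry_angle=%.10g", angle),
      sprintf("# pressure_hpa=%.10g", conditions$pressure),
      sprintf("# temperature_k=%.10g", conditions$temperature),
      sprintf("# calibration_factor=%.10g", geometry$calibration_factor)
    )
    con <- file(rpath, "w")
    writeLines(header, con)
    utils::write.csv(format_numeric_df(rec), con, row.names = FALSE,
                     quote = FALSE)
    close(con)
    record_paths <- c(record_paths, rpath)

    ev <- fraction$events[fraction$events$field_id == fid, ]
    epath <- file.path(dir, sprintf("events_f%03d_%s.jsonl",
                                    fraction$fraction_index, fid))
    lines <- vapply(seq_len(nrow(ev)), function(i) {
      jsonlite::toJSON(list(t_us = ev$t_us[i], kind = ev$kind[i],
                            payload = ev$payload[i]),
                       auto_unbox = TRUE, digits = NA)
    }, character(1))
    writeLines(lines, epath)
    events_paths <- c(events_paths, epath)
  }
  invisible(list(record_paths = record_paths, events_paths = events_paths))
}

#' Read record and events log files into a fraction log
#'
#' Parses one record CSV per delivered field plus the matching events files,
#' reconstructs isocenter-plane spot positions (intercept-theorem projection
#' per axis) and MU (charge times calibration factor with air density
#' correction from the file header), matches spots to the plan by
#' `(field_id, layer_index, spot_index)` and flags the fraction as aborted
#' when fewer spots were logged than planned.
#'
#' Position columns are accepted either as IC-plane values
#' (`x_ic_mm`/`y_ic_mm`, projected on read) together with `charge`, or
#' pre-projected as `x_mm`/`y_mm` together with `mu`.
#'
#' @param record_paths Paths to the record CSV files (one per field).
#' @param events_paths Paths to the events JSON-lines files.
#' @param plan The `lfqa_plan` the delivery belongs to.
#' @param geometry A [machine_geometry()].
#' @param fraction_index Fraction number to attach, >= 1.
#' @return A `fraction_log`.
#' @export
read_fraction <- function(record_paths, events_paths, plan,
                          geometry = machine_geometry(),
                          fraction_index = 1L) {
  spots <- purrr::map_dfr(record_paths, read_record_file, geometry = geometry)
  dup <- duplicated(spots[, spot_key_cols])
  if (any(dup)) {
    stop_lfqa(
      sprintf("duplicate spot key in record files: %s/%d/%d",
              spots$field_id[dup][1], spots$layer_index[dup][1],
              spots$spot_index[dup][1]),
      "lfqa_integrity_error"
    )
  }
  events <- purrr::map_dfr(events_paths, read_events_file)
  # order spots by drill start within each field, fields by first appearance
  spots <- spots |>
    dplyr::group_by(.data$field_id) |>
    dplyr::arrange(.data$t_start_us, .by_group = TRUE) |>
    dplyr::ungroup()
  unknown <- dplyr::anti_join(spots, plan, by = spot_key_cols)
  if (nrow(unknown) > 0) {
    stop_lfqa(
      sprintf("logged spot %s/%d/%d has no planned counterpart",
              unknown$field_id[1], unknown$layer_index[1],
              unknown$spot_index[1]),
      "lfqa_integrity_error"
    )
  }
  new_fraction_log(
    fraction_index = as.integer(fraction_index),
    spots = spots[, c("field_id", "layer_index", "spot_index",
                      "x_mm", "y_mm", "mu", "t_start_us", "t_end_us")],
    events = events,
    aborted = nrow(spots) < nrow(plan)
  )
}

read_record_file <- function(path, geometry) {
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  hdr <- parse_record_header(lines[hdr_idx])
  body <- lines[setdiff(seq_along(lines), hdr_idx)]
  df <- tryCatch(
    utils::read.csv(text = body, stringsAsFactors = FALSE),
    error = function(e) {
      stop_lfqa(sprintf("%s: cannot parse record table: %s", path,
                        conditionMessage(e)), "lfqa_format_error")
    }
  )
  need_common <- c("layer_index", "spot_index", "t_start_us", "t_end_us")
  ic_dialect <- all(c("x_ic_mm", "y_ic_mm", "charge") %in% names(df))
  iso_dialect <- all(c("x_mm", "y_mm", "mu") %in% names(df))
  if (!all(need_common %in% names(df)) || !(ic_dialect || iso_dialect)) {
    stop_lfqa(sprintf("%s: unknown record dialect (columns: %s)", path,
                      paste(names(df), collapse = ", ")),
              "lfqa_format_error")
  }
  bad <- which(!stats::complete.cases(df))
  if (length(bad) > 0) {
    data_line <- setdiff(seq_along(lines), hdr_idx)[bad + 1L]  # +1: header row
    stop_lfqa(sprintf("%s: malformed row(s) at line %s", path,
                      paste(data_line, collapse = ", ")),
              "lfqa_format_error")
  }
  if (ic_dialect) {
    conditions <- ambient_conditions(hdr$pressure_hpa, hdr$temperature_k)
    x_mm <- project_to_isocenter(df$x_ic_mm, "x", geometry)
    y_mm <- project_to_isocenter(df$y_ic_mm, "y", geometry)
    mu <- charge_to_mu(df$charge, hdr$calibration_factor, conditions, geometry)
  } else {
    x_mm <- df$x_mm; y_mm <- df$y_mm; mu <- df$mu
  }
  tibble::tibble(
    field_id = hdr$field_id,
    gantry_angle = hdr$gantry_angle,
    layer_index = as.integer(df$layer_index),
    spot_index = as.integer(df$spot_index),
    x_mm = x_mm, y_mm = y_mm, mu = mu,
    t_start_us = as.numeric(df$t_start_us),
    t_end_us = as.numeric(df$t_end_us)
  )
}

parse_record_header <- function(hlines) {
  kv <- sub("^#\\s*", "", hlines)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  h <- as.list(setNames(vals, keys))
  for (k in c("gantry_angle", "pressure_hpa", "temperature_k",
              "calibration_factor")) {
    if (!is.null(h[[k]])) h[[k]] <- as.numeric(h[[k]])
  }
  if (is.null(h$field_id)) {
    stop_lfqa("record header is missing `field_id`", "lfqa_format_error")
  }
  h
}

read_events_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fid <- sub("^events_f[0-9]+_(.*)\\.jsonl$", "\\1", basename(path))
  purrr::map_dfr(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln)
    tibble::tibble(field_id = fid, t_us = as.numeric(obj$t_us),
                   kind = obj$kind, payload = as.character(obj$payload))
  })
}
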