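#' Minimum deliverable spot weight (MU)
#'
#' Spot weights below this floor cannot be delivered by the machine; planned
#' spots are always at or above it.
#' @export
MU_FLOOR <- 0.014

#' Generate a synthetic PBS treatment plan
#'
#' Lays spots on a regular scan-line grid inside a disc, one grid per energy
#' layer, for one or more fields at the requested gantry angles. Spot weights
#' are drawn from a log-normal distribution truncated at the minimum
#' deliverable spot MU, with heavier spots towards the lateral edge of the
#' disc (as field-edge spots typically carry more weight in clinical plans).
#' Energies decrease layer by layer from `energy_max` to `energy_min`.
#'
#' The plan is returned as a flat tibble, one row per spot, with class
#' `lfqa_plan`; the field -> layer -> spot hierarchy is carried by the
#' `field_id`, `layer_index` and `spot_index` key columns.
#'
#' @param n_fields Number of fields (>= 1).
#' @param gantry_angles Gantry angle per field, degrees in `[0, 360)`.
#' @param layers_per_field Number of energy layers per field (>= 1).
#' @param spots_per_layer Number of spots per layer (>= 1).
#' @param target_radius Radius of the target disc in the beam's eye view (mm).
#' @param rng_seed Integer seed; identical inputs and seed give byte-identical
#'   plans.
#' @param plan_id Plan identifier.
#' @param energy_min,energy_max Energy range spanned by the layers (MeV).
#' @param spot_spacing Scan grid pitch (mm); by default chosen so the disc
#'   holds at least `spots_per_layer` grid points.
#' @param mu_mean Geometric mean of the spot weight distribution (MU).
#'
#' @return A tibble of class `lfqa_plan` with columns `plan_id`, `field_id`,
#'   `gantry_angle`, `layer_index`, `energy_mev`, `spot_index`, `x_mm`,
#'   `y_mm`, `mu`. The scan pitch is stored in attribute `spot_spacing`.
#' @export
#' @examples
#' plan <- generate_plan(2, c(90, 270), layers_per_field = 3,
#'                       spots_per_layer = 40, target_radius = 40, rng_seed = 1)
#' dplyr::count(plan, field_id, layer_index)
generate_plan <- function(n_fields, gantry_angles, layers_per_field,
                          spots_per_layer, target_radius, rng_seed,
                          plan_id = "synthetic-plan",
                          energy_min = 90, energy_max = 110,
                          spot_spacing = NULL,
                          mu_mean = 0.04) {
  if (n_fields < 1 || layers_per_field < 1 || spots_per_layer < 1) {
    stop_lfqa("field, layer and spot counts must all be >= 1",
              "lfqa_invalid_argument")
  }
  if (length(gantry_angles) != n_fields) {
    stop_lfqa("`gantry_angles` must have one angle per field",
              "lfqa_invalid_argument")
  }
  if (any(gantry_angles < 0 | gantry_angles >= 360)) {
    stop_lfqa("gantry angles must lie in [0, 360)", "lfqa_invalid_argument")
  }
  assert_scalar_number(target_radius, "target_radius", 0, strict = TRUE)

  # Scan-line grid: serpentine row order (row-major, alternating direction),
  # restricted to the disc. Pitch chosen so the disc holds enough points.
  if (is.null(spot_spacing)) {
    spot_spacing <- max(2 * target_radius / (ceiling(sqrt(spots_per_layer)) + 1),
                        1e-3)
    while (nrow(scan_grid(target_radius, spot_spacing)) < spots_per_layer) {
      spot_spacing <- spot_spacing * 0.9
    }
  }
  grid <- scan_grid(target_radius, spot_spacing)
  if (nrow(grid) < spots_per_layer) {
    stop_lfqa("`spot_spacing` too coarse for the requested spots_per_layer",
              "lfqa_invalid_argument")
  }
  grid <- grid[seq_len(spots_per_layer), , drop = FALSE]

  energies <- if (layers_per_field == 1) {
    energy_max
  } else {
    seq(energy_max, energy_min, length.out = layers_per_field)
  }

  spots <- with_substream(substream_seed(rng_seed, 101), {
    purrr::map_dfr(seq_len(n_fields), function(f) {
      purrr::map_dfr(seq_len(layers_per_field), function(l) {
        # Edge weighting: spots near the disc rim get larger MU on average.
        r_frac <- hypot(grid$x, grid$y) / target_radius
        mu <- rlnorm(spots_per_layer,
                     meanlog = log(mu_mean) + 0.8 * r_frac^2,
                     sdlog = 0.45)
        tibble::tibble(
          plan_id = plan_id,
          field_id = sprintf("F%02d", f),
          gantry_angle = gantry_angles[f],
          layer_index = l - 1L,
          energy_mev = energies[l],
          spot_index = seq_len(spots_per_layer) - 1L,
          x_mm = grid$x,
          y_mm = grid$y,
          mu = pmax(mu, MU_FLOOR)
        )
      })
    })
  })
  new_lfqa_plan(spots, spot_spacing = spot_spacing)
}

new_lfqa_plan <- function(spots, spot_spacing = NA_real_) {
  out <- tibble::as_tibble(spots)
  attr(out, "spot_spacing") <- spot_spacing
  class(out) <- c("lfqa_plan", class(tibble::tibble()))
  out
}

scan_grid <- function(radius, pitch) {
  half <- floor(radius / pitch)
  ys <- seq(-half, half) * pitch
  rows <- lapply(seq_along(ys), function(i) {
    y <- ys[i]
    xmax <- sqrt(max(radius^2 - y^2, 0))
    xs <- seq(-floor(xmax / pitch), floor(xmax / pitch)) * pitch
    if (i %% 2 == 0) xs <- rev(xs)   # serpentine scanning
    data.frame(x = xs, y = y)
  })
  tibble::as_tibble(do.call(rbind, rows))
}

plan_spot_count <- function(plan) nrow(plan)

#' Write / read a treatment plan
#'
#' `write_plan_json()` stores the nested plan -> fields -> layers -> spots
#' structure; `write_plan_csv()` stores the flat per-spot table
#' (`field_id,gantry_angle,layer_index,energy_mev,spot_index,x_mm,y_mm,mu`).
#' The readers invert them.
#'
#' @param plan An `lfqa_plan` tibble.
#' @param path File path.
#' @return The input `plan` (writers, invisibly) or an `lfqa_plan` (readers).
#' @export
write_plan_json <- function(plan, path) {
  fields <- plan |>
    dplyr::group_by(.data$field_id, .data$gantry_angle) |>
    dplyr::group_map(function(fd, key) {
      layers <- fd |>
        dplyr::group_by(.data$layer_index, .data$energy_mev) |>
        dplyr::group_map(function(ld, lkey) {
          list(
            layer_index = lkey$layer_index,
            energy_mev = lkey$energy_mev,
            spots = lapply(seq_len(nrow(ld)), function(i) {
              list(spot_index = ld$spot_index[i], x_mm = ld$x_mm[i],
                   y_mm = ld$y_mm[i], mu = ld$mu[i])
            })
          )
        })
      list(field_id = key$field_id, gantry_angle = key$gantry_angle,
           layers = layers)
    })
  obj <- list(plan_id = plan$plan_id[1],
              spot_spacing = attr(plan, "spot_spacing"),
              fields = fields)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(plan)
}

#' @rdname write_plan_json
#' @export
read_plan_json <- function(path) {
  obj <- jsonlite::read_json(path)
  rows <- purrr::map_dfr(obj$fields, function(fd) {
    purrr::map_dfr(fd$layers, function(ld) {
      purrr::map_dfr(ld$spots, function(sp) {
        tibble::tibble(
          plan_id = obj$plan_id,
          field_id = fd$field_id,
          gantry_angle = as.numeric(fd$gantry_angle),
          layer_index = as.integer(ld$layer_index),
          energy_mev = as.numeric(ld$energy_mev),
          spot_index = as.integer(sp$spot_index),
          x_mm = as.numeric(sp$x_mm),
          y_mm = as.numeric(sp$y_mm),
          mu = as.numeric(sp$mu)
        )
      })
    })
  })
  new_lfqa_plan(rows, spot_spacing = as.numeric(obj$spot_spacing %||% NA_real_))
}

#' @rdname write_plan_json
#' @export
write_plan_csv <- function(plan, path) {
  df <- plan[, c("field_id", "gantry_angle", "layer_index", "energy_mev",
                 "spot_index", "x_mm", "y_mm", "mu")]
  utils::write.csv(format_numeric_df(df), path, row.names = FALSE,
                   quote = FALSE)
  invisible(plan)
}

#' @rdname write_plan_json
#' @param plan_id Plan identifier to attach (the flat CSV does not carry one).
#' @export
read_plan_csv <- function(path, plan_id = "plan") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  new_lfqa_plan(tibble::tibble(
    plan_id = plan_id,
    field_id = as.character(df$field_id),
    gantry_angle = as.numeric(df$gantry_angle),
    layer_index = as.integer(df$layer_index),
    energy_mev = as.numeric(df$energy_mev),
    spot_index = as.integer(df$spot_index),
    x_mm = as.numeric(df$x_mm),
    y_mm = as.numeric(df$y_mm),
    mu = as.numeric(df$mu)
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Full-precision numeric text so writer/reader round-trips are lossless at
# the level of written decimal text.
format_numeric_df <- function(df, digits = 17) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- formatC(df[[nm]], digits = digits,
                                                 format = "g")
  }
  df
}
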