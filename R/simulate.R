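#' Simulate the delivery of one treatment fraction
#'
#' Applies the machine [error_model()] to every planned spot and builds the
#' delivery time structure, producing a `fraction_log`: the per-spot record
#' (isocenter-plane positions, delivered MU, drill start/end timestamps) and
#' the event stream (field/layer markers, interlock pairs).
#'
#' The delivered position of a spot is
#' `plan + systematic + layer tuning shift + noise`, where the systematic
#' part is the gantry-angle x offset plus the per-scan-row y offset, the
#' layer tuning shift is a per-(layer, fraction) random y shift, and the
#' per-spot noise SD is inflated for high-MU spots on the lateral field edge
#' (within one scan pitch of the layer's convex hull). Delivered MU is
#' `plan + bias + noise`, clipped at zero (a delivered spot may record
#' slightly below the plannable minimum). Timestamps are integer
#' microseconds: drill time proportional to delivered MU, spot-switch gaps
#' within a layer, energy-switch gaps between layers, and optional interlock
#' intervals inserted into a gap.
#'
#' Randomness is drawn from substreams derived from
#' `(rng_seed, fraction_index, field, layer)`, so each fraction is
#' independent but reproducible and adding fractions never perturbs earlier
#' ones. Scan-row offsets use fraction-independent streams, making them
#' systematic across fractions.
#'
#' @param plan An [generate_plan()] tibble.
#' @param geometry A [machine_geometry()].
#' @param errors An [error_model()].
#' @param fraction_index Fraction number, >= 1.
#' @return An object of class `fraction_log`: a list with elements
#'   `fraction_index`, `spots` (tibble: `field_id`, `layer_index`,
#'   `spot_index`, `x_mm`, `y_mm`, `mu`, `t_start_us`, `t_end_us`), `events`
#'   (tibble: `field_id`, `t_us`, `kind`, `payload`) and `aborted`. The
#'   generator's per-field timing bookkeeping (drill, spot-switch,
#'   energy-switch, interlock totals in microseconds) is stored in attribute
#'   `timing_truth`.
#' @export
simulate_fraction <- function(plan, geometry = machine_geometry(),
                              errors = error_model(), fraction_index = 1L) {
  if (fraction_index < 1) {
    stop_lfqa("`fraction_index` must be >= 1", "lfqa_invalid_argument")
  }
  seed <- errors$rng_seed
  pitch <- attr(plan, "spot_spacing")
  field_ids <- unique(plan$field_id)

  spot_rows <- vector("list", 0L)
  event_rows <- vector("list", 0L)
  truth_rows <- vector("list", 0L)

  for (f in seq_along(field_ids)) {
    fid <- field_ids[f]
    fplan <- plan[plan$field_id == fid, ]
    angle <- fplan$gantry_angle[1]
    layers <- sort(unique(fplan$layer_index))

    x_sys <- errors$x_offset_amplitude * errors$x_offset_angle_profile(angle)

    t <- (f - 1) * 9e8  # inter-field beam-off gap; never part of delivery time
    field_t0 <- t
    event_rows[[length(event_rows) + 1L]] <-
      event_tbl(fid, t, "FIELD_START", fid)

    drill_total <- 0; ss_total <- 0; es_total <- 0; il_total <- 0

    # One interlock at most per field delivery, inserted into a random gap.
    il <- with_substream(substream_seed(seed, fraction_index, f, 100000L), {
      if (runif(1) < errors$interlock_probability_per_field) {
        dur_s <- max(rnorm(1, errors$interlock_duration_s,
                           errors$interlock_duration_sd_s), 0.5)
        list(dur_us = round(dur_s * 1e6),
             at_layer = if (length(layers) > 1) sample(layers[-1], 1) else layers[1],
             at_spot = sample(max(nrow(fplan[fplan$layer_index == layers[1], ]) - 1L, 1L), 1))
      } else NULL
    })

    for (li in seq_along(layers)) {
      l <- layers[li]
      lplan <- fplan[fplan$layer_index == l, ]
      n <- nrow(lplan)

      # Fraction-independent systematic per-scan-row y offsets.
      row_id <- match(lplan$y_mm, sort(unique(lplan$y_mm)))
      row_off <- with_substream(substream_seed(seed, 0L, f, l), {
        runif(length(unique(row_id)), -1, 1) * errors$y_row_offset
      })[row_id]

      lpitch <- if (is.finite(pitch)) pitch else estimate_pitch(lplan$x_mm, lplan$y_mm)
      hot <- lplan$mu >= errors$highmu_threshold &
        edge_spots(lplan$x_mm, lplan$y_mm, lpitch)
      sd_eff <- errors$position_noise_sd *
        ifelse(hot, errors$edge_highmu_noise_multiplier, 1)

      draw <- with_substream(substream_seed(seed, fraction_index, f, l), {
        list(
          tune = rnorm(1, 0, errors$layer_tune_shift_sd),
          nx = rnorm(n, 0, 1),
          ny = rnorm(n, 0, 1),
          nmu = rnorm(n, 0, 1),
          ss = pmax(rnorm(max(n - 1, 0), errors$spot_switch_time_ms,
                          errors$spot_switch_time_sd_ms), 0),
          es = pmax(rnorm(1, errors$energy_switch_time_s,
                          errors$energy_switch_time_sd_s), 0)
        )
      })

      x_log <- lplan$x_mm + x_sys + sd_eff * draw$nx
      y_log <- lplan$y_mm + row_off + draw$tune + sd_eff * draw$ny
      mu_log <- pmax(lplan$mu + errors$mu_bias + errors$mu_noise_sd * draw$nmu, 0)

      # --- timing (integer microseconds throughout) ---
      if (li > 1) {
        es_us <- round(draw$es * 1e6)
        if (!is.null(il) && il$at_layer == l && length(layers) > 1) {
          # interlock splits this energy-switch gap
          il_start <- t + es_us %/% 2
          event_rows[[length(event_rows) + 1L]] <-
            event_tbl(fid, il_start, "INTERLOCK_START", "beam interrupted")
          event_rows[[length(event_rows) + 1L]] <-
            event_tbl(fid, il_start + il$dur_us, "INTERLOCK_END", "beam resumed")
          t <- t + es_us + il$dur_us
          il_total <- il_total + il$dur_us
        } else {
          t <- t + es_us
        }
        es_total <- es_total + es_us
      }
      event_rows[[length(event_rows) + 1L]] <-
        event_tbl(fid, t, "LAYER_START", sprintf("layer %d", l))

      drill_us <- round(errors$drill_time_per_mu * mu_log * 1000)
      ss_us <- round(draw$ss * 1000)
      t_start <- numeric(n); t_end <- numeric(n)
      for (s in seq_len(n)) {
        t_start[s] <- t
        t <- t + drill_us[s]
        t_end[s] <- t
        if (s < n) {
          gap <- ss_us[s]
          if (!is.null(il) && length(layers) == 1 && il$at_layer == l &&
              il$at_spot == s) {
            il_start <- t + gap %/% 2
            event_rows[[length(event_rows) + 1L]] <-
              event_tbl(fid, il_start, "INTERLOCK_START", "beam interrupted")
            event_rows[[length(event_rows) + 1L]] <-
              event_tbl(fid, il_start + il$dur_us, "INTERLOCK_END", "beam resumed")
            t <- t + gap + il$dur_us
            il_total <- il_total + il$dur_us
          } else {
            t <- t + gap
          }
          ss_total <- ss_total + gap
        }
      }
      drill_total <- drill_total + sum(drill_us)
      event_rows[[length(event_rows) + 1L]] <-
        event_tbl(fid, t, "LAYER_END", sprintf("layer %d", l))

      spot_rows[[length(spot_rows) + 1L]] <- tibble::tibble(
        field_id = fid,
        layer_index = lplan$layer_index,
        spot_index = lplan$spot_index,
        x_mm = x_log, y_mm = y_log, mu = mu_log,
        t_start_us = t_start, t_end_us = t_end
      )
    }
    event_rows[[length(event_rows) + 1L]] <- event_tbl(fid, t, "FIELD_END", fid)
    truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
      field_id = fid, drill_us = drill_total, spot_switch_us = ss_total,
      energy_switch_us = es_total, interlock_us = il_total,
      field_span_us = t - field_t0
    )
  }

  new_fraction_log(
    fraction_index = as.integer(fraction_index),
    spots = dplyr::bind_rows(spot_rows),
    events = dplyr::bind_rows(event_rows),
    aborted = FALSE,
    timing_truth = dplyr::bind_rows(truth_rows)
  )
}

event_tbl <- function(field_id, t_us, kind, payload) {
  tibble::tibble(field_id = field_id, t_us = t_us, kind = kind,
                 payload = payload)
}

new_fraction_log <- function(fraction_index, spots, events, aborted,
                             timing_truth = NULL) {
  structure(
    list(fraction_index = fraction_index, spots = spots, events = events,
         aborted = aborted),
    timing_truth = timing_truth,
    class = "fraction_log"
  )
}

#' @export
print.fraction_log <- function(x, ...) {
  cat(sprintf("<fraction_log> fraction %d: %d spots, %d events%s\n",
              x$fraction_index, nrow(x$spots), nrow(x$events),
              if (x$aborted) " (aborted)" else ""))
  invisible(x)
}

#' Simulate a course of N fractions
#'
#' @inheritParams simulate_fraction
#' @param n_fractions Number of fractions to simulate.
#' @return List of [simulate_fraction()] results, one per fraction.
#' @export
simulate_course <- function(plan, geometry = machine_geometry(),
                            errors = error_model(), n_fractions = 15L) {
  purrr::map(seq_len(n_fractions), function(i) {
    simulate_fraction(plan, geometry, errors, fraction_index = i)
  })
}

#' Truncate a fraction log to emulate a prematurely aborted delivery
#'
#' Keeps only the first `after_layers` energy layers of `field_id` (and all
#' preceding fields), drops everything later, and marks the log aborted.
#'
#' @param fraction A `fraction_log`.
#' @param field_id Field in which the abort occurred.
#' @param after_layers Number of layers of that field that were delivered.
#' @return The truncated `fraction_log` with `aborted = TRUE`.
#' @export
abort_fraction <- function(fraction, field_id, after_layers) {
  sp <- fraction$spots
  fids <- unique(sp$field_id)
  f_at <- match(field_id, fids)
  if (is.na(f_at)) stop_lfqa("unknown field_id", "lfqa_invalid_argument")
  keep_layers <- sort(unique(sp$layer_index[sp$field_id == field_id]))
  keep_layers <- head(keep_layers, after_layers)
  keep <- sp$field_id %in% fids[seq_len(f_at - 1)] |
    (sp$field_id == field_id & sp$layer_index %in% keep_layers)
  cutoff <- max(sp$t_end_us[keep])
  ev <- fraction$events
  ev_keep <- ev$field_id %in% fids[seq_len(f_at - 1)] |
    (ev$field_id == field_id & ev$t_us <= cutoff)
  new_fraction_log(fraction$fraction_index, sp[keep, ], ev[ev_keep, ],
                   aborted = TRUE)
}

# Spots on the lateral field edge: within one scan pitch of the layer's 2D
# convex hull boundary.
edge_spots <- function(x, y, pitch) {
  n <- length(x)
  if (n <= 3) return(rep(TRUE, n))
  hull <- grDevices::chull(x, y)
  hx <- x[hull]; hy <- y[hull]
  m <- length(hull)
  d2min <- rep(Inf, n)
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    d2min <- pmin(d2min, point_segment_dist2(x, y, hx[i], hy[i], hx[j], hy[j]))
  }
  sqrt(d2min) <= pitch * (1 + 1e-9)
}

point_segment_dist2 <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  len2 <- vx^2 + vy^2
  t <- if (len2 == 0) 0 else pmin(pmax(((px - ax) * vx + (py - ay) * vy) / len2, 0), 1)
  (px - (ax + t * vx))^2 + (py - (ay + t * vy))^2
}

estimate_pitch <- function(x, y) {
  ys <- sort(unique(y))
  if (length(ys) > 1) min(diff(ys)) else {
    xs <- sort(unique(x))
    if (length(xs) > 1) min(diff(xs)) else 1
  }
}
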