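#' Decompose a field delivery into drill, switching and interlock time
#'
#' Splits one field's delivery, as recorded in the log timestamps, into
#' cumulative components: spot drill time (beam-on, `t_end - t_start` per
#' spot), spot switching (gaps between consecutive spots within an energy
#' layer), energy switching (gaps between the last spot of a layer and the
#' first of the next), and machine interlock time. Any portion of a drill or
#' gap interval covered by an `INTERLOCK_START`/`INTERLOCK_END` pair is
#' attributed to `interlock_total` and excised from its category, so the
#' delivery time (drill + spot switch + energy switch) excludes
#' interruptions. Beam-off time between fields is never counted. Layer
#' boundaries are taken from `layer_index` changes in the record.
#'
#' @param spots One field's logged spots, time-ordered (tibble with
#'   `layer_index`, `t_start_us`, `t_end_us`).
#' @param events The field's event stream (tibble with `t_us`, `kind`).
#' @param fraction_index,field_id Identifiers carried into the output.
#' @return A one-row tibble: `field_id`, `fraction_index`, `drill_total`,
#'   `spot_switch_total`, `energy_switch_total`, `interlock_total`,
#'   `delivery_time` (all seconds) and `had_interlock`.
#' @export
decompose_field_timing <- function(spots, events, fraction_index = NA_integer_,
                                   field_id = NULL) {
  if (nrow(spots) == 0) stop_lfqa("no spots", "lfqa_invalid_data")
  if (is.unsorted(spots$t_start_us)) {
    stop_lfqa("spot timestamps are not monotone", "lfqa_invalid_data")
  }
  if (any(spots$t_end_us < spots$t_start_us)) {
    stop_lfqa("spot with t_end < t_start", "lfqa_invalid_data")
  }
  field_id <- field_id %||% (if ("field_id" %in% names(spots))
    spots$field_id[1] else NA_character_)

  il <- interlock_intervals(events)

  n <- nrow(spots)
  drill_a <- spots$t_start_us
  drill_b <- spots$t_end_us
  drill_us <- sum(drill_b - drill_a) - overlap_total(drill_a, drill_b, il)

  ss_us <- 0; es_us <- 0
  if (n > 1) {
    gap_a <- spots$t_end_us[-n]
    gap_b <- spots$t_start_us[-1]
    same_layer <- spots$layer_index[-n] == spots$layer_index[-1]
    gap_len <- (gap_b - gap_a) - overlap_by_interval(gap_a, gap_b, il)
    ss_us <- sum(gap_len[same_layer])
    es_us <- sum(gap_len[!same_layer])
  }
  il_us <- overlap_total(min(drill_a), max(drill_b), il)

  tibble::tibble(
    field_id = field_id,
    fraction_index = as.integer(fraction_index),
    drill_total = drill_us / 1e6,
    spot_switch_total = ss_us / 1e6,
    energy_switch_total = es_us / 1e6,
    interlock_total = il_us / 1e6,
    delivery_time = (drill_us + ss_us + es_us) / 1e6,
    had_interlock = nrow(il) > 0
  )
}

# Paired interlock intervals from an event stream; START/END must strictly
# alternate.
interlock_intervals <- function(events) {
  ev <- events[events$kind %in% c("INTERLOCK_START", "INTERLOCK_END"), ]
  ev <- ev[order(ev$t_us), ]
  if (nrow(ev) == 0) {
    return(tibble::tibble(a = numeric(0), b = numeric(0)))
  }
  expected <- rep(c("INTERLOCK_START", "INTERLOCK_END"), length.out = nrow(ev))
  if (nrow(ev) %% 2 != 0 || !all(ev$kind == expected)) {
    stop_lfqa("interlock events do not strictly alternate start/end",
              "lfqa_integrity_error")
  }
  tibble::tibble(a = ev$t_us[c(TRUE, FALSE)], b = ev$t_us[c(FALSE, TRUE)])
}

# Total overlap of the union of [a_i, b_i] with the interlock intervals.
overlap_total <- function(a, b, il) {
  sum(overlap_by_interval(a, b, il))
}

overlap_by_interval <- function(a, b, il) {
  if (nrow(il) == 0) return(numeric(length(a)))
  vapply(seq_along(a), function(i) {
    sum(pmax(pmin(b[i], il$b) - pmax(a[i], il$a), 0))
  }, numeric(1))
}

#' Timing decomposition of a whole fraction
#'
#' Runs [decompose_field_timing()] for every field of a fraction log.
#'
#' @param fraction A `fraction_log`.
#' @return A tibble with one row per field.
#' @export
decompose_timing <- function(fraction) {
  purrr::map_dfr(unique(fraction$spots$field_id), function(fid) {
    decompose_field_timing(
      fraction$spots[fraction$spots$field_id == fid, ],
      fraction$events[fraction$events$field_id == fid, ],
      fraction_index = fraction$fraction_index,
      field_id = fid
    )
  })
}

#' Delivery-time reproducibility summary
#'
#' Summarises timing breakdowns across fractions: per field and per plan,
#' the mean delivery time (excluding interlocks) and its double corrected
#' sample standard deviation (2 sigma, the reproducibility band), plus the
#' percentage of field deliveries without any machine interlock.
#'
#' @param breakdowns Tibble of [decompose_field_timing()] rows over fields
#'   and fractions.
#' @return A tibble with columns `level` (`"field"` or `"plan"`), `id`,
#'   `n`, `mean_delivery_time`, `two_sigma`, `interlock_free_percent`.
#' @export
timing_summary <- function(breakdowns) {
  if (nrow(breakdowns) == 0) stop_lfqa("no breakdowns", "lfqa_invalid_data")
  per_field <- breakdowns |>
    dplyr::group_by(.data$field_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_delivery_time = mean(.data$delivery_time),
      two_sigma = 2 * sd(.data$delivery_time),
      interlock_free_percent = 100 * mean(!.data$had_interlock),
      .groups = "drop"
    ) |>
    dplyr::mutate(level = "field") |>
    dplyr::rename(id = "field_id")
  per_plan <- breakdowns |>
    dplyr::group_by(.data$fraction_index) |>
    dplyr::summarise(plan_time = sum(.data$delivery_time),
                     any_interlock = any(.data$had_interlock),
                     .groups = "drop") |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_delivery_time = mean(.data$plan_time),
      two_sigma = 2 * sd(.data$plan_time),
      interlock_free_percent = 100 * mean(!breakdowns$had_interlock)
    ) |>
    dplyr::mutate(level = "plan", id = "all")
  dplyr::bind_rows(per_field, per_plan)[, c("level", "id", "n",
                                            "mean_delivery_time", "two_sigma",
                                            "interlock_free_percent")]
}
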