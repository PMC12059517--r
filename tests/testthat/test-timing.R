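# Construct a synthetic single-field log: 2 layers x 50 spots, drill 10 ms,
# spot switch 2 ms, one energy switch of 1 s.
constructed_field <- function(interlock_at = NULL, interlock_us = 3e7) {
  t <- 0
  rows <- list()
  events <- list(tibble::tibble(field_id = "F01", t_us = 0,
                                kind = "FIELD_START", payload = "F01"))
  for (l in 0:1) {
    for (s in 0:49) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        field_id = "F01", layer_index = l, spot_index = s,
        t_start_us = t, t_end_us = t + 1e4
      )
      t <- t + 1e4
      if (s < 49) t <- t + 2e3
    }
    if (l == 0) {
      gap <- 1e6
      if (identical(interlock_at, "energy_switch")) {
        events[[length(events) + 1]] <- tibble::tibble(
          field_id = "F01", t_us = t + gap / 2, kind = "INTERLOCK_START",
          payload = "")
        events[[length(events) + 1]] <- tibble::tibble(
          field_id = "F01", t_us = t + gap / 2 + interlock_us,
          kind = "INTERLOCK_END", payload = "")
        t <- t + gap + interlock_us
      } else {
        t <- t + gap
      }
    }
  }
  list(spots = dplyr::bind_rows(rows), events = dplyr::bind_rows(events))
}

test_that("drill, spot-switch and energy-switch components add up", {
  fl <- constructed_field()
  tm <- decompose_field_timing(fl$spots, fl$events, 1, "F01")
  expect_equal(tm$drill_total, 1.0)          # 100 spots x 10 ms
  expect_equal(tm$spot_switch_total, 0.196)  # 98 gaps x 2 ms
  expect_equal(tm$energy_switch_total, 1.0)
  expect_equal(tm$delivery_time,
               tm$drill_total + tm$spot_switch_total + tm$energy_switch_total)
  expect_false(tm$had_interlock)
})

test_that("an interlock inside an energy-switch gap is excised neutrally", {
  clean <- constructed_field()
  hit <- constructed_field(interlock_at = "energy_switch", interlock_us = 3e7)
  tm_clean <- decompose_field_timing(clean$spots, clean$events, 1, "F01")
  tm_hit <- decompose_field_timing(hit$spots, hit$events, 1, "F01")
  expect_equal(tm_hit$energy_switch_total, tm_clean$energy_switch_total)
  expect_equal(tm_hit$drill_total, tm_clean$drill_total)
  expect_equal(tm_hit$spot_switch_total, tm_clean$spot_switch_total)
  expect_equal(tm_hit$interlock_total, 30)
  expect_equal(tm_hit$delivery_time, tm_clean$delivery_time)
  expect_true(tm_hit$had_interlock)
})

test_that("malformed event streams and timestamps are rejected", {
  fl <- constructed_field(interlock_at = "energy_switch")
  ev_unpaired <- fl$events[fl$events$kind != "INTERLOCK_END", ]
  expect_error(decompose_field_timing(fl$spots, ev_unpaired, 1, "F01"),
               class = "lfqa_integrity_error")
  sp_bad <- fl$spots
  sp_bad$t_start_us[10] <- sp_bad$t_start_us[30]
  expect_error(decompose_field_timing(sp_bad[order(sp_bad$spot_index), ],
                                      fl$events, 1, "F01"),
               class = "lfqa_invalid_data")
})

test_that("components reproduce the simulator's bookkeeping to 1 microsecond", {
  plan <- tiny_plan(2, c(120, 300), layers = 3, spots = 12)
  geo <- machine_geometry()
  err <- error_model(position_noise_sd = 0.1, spot_switch_time_sd_ms = 0.4,
                     energy_switch_time_sd_s = 0.3,
                     interlock_probability_per_field = 0.7, rng_seed = 21)
  for (i in 1:3) {
    fr <- simulate_fraction(plan, geo, err, i)
    truth <- attr(fr, "timing_truth")
    tm <- decompose_timing(fr)
    m <- dplyr::inner_join(tm, truth, by = "field_id")
    expect_equal(m$drill_total * 1e6, m$drill_us, tolerance = 1e-6)
    expect_equal(m$spot_switch_total * 1e6, m$spot_switch_us, tolerance = 1e-6)
    expect_equal(m$energy_switch_total * 1e6, m$energy_switch_us,
                 tolerance = 1e-6)
    expect_equal(m$interlock_total * 1e6, m$interlock_us, tolerance = 1e-6)
    # conservation: components span first-to-last timestamp exactly
    span <- vapply(unique(fr$spots$field_id), function(fid) {
      sp <- fr$spots[fr$spots$field_id == fid, ]
      max(sp$t_end_us) - min(sp$t_start_us)
    }, numeric(1))
    total <- (m$drill_total + m$spot_switch_total + m$energy_switch_total +
                m$interlock_total) * 1e6
    expect_equal(unname(total), unname(span), tolerance = 1e-6)
  }
})

test_that("timing summaries report 2 sigma reproducibility and interlock rate", {
  br <- tibble::tibble(
    field_id = rep(sprintf("F%02d", 1:14), each = 1),
    fraction_index = 1L,
    drill_total = 10, spot_switch_total = 1, energy_switch_total = 5,
    interlock_total = c(rep(0, 13), 40),
    delivery_time = 16,
    had_interlock = c(rep(FALSE, 13), TRUE)
  )
  ts <- timing_summary(br)
  plan_row <- ts[ts$level == "plan", ]
  expect_equal(plan_row$interlock_free_percent, 100 * 13 / 14,
               tolerance = 1e-12)

  # identical repeated deliveries have zero spread
  br2 <- dplyr::bind_rows(
    dplyr::mutate(br[1:2, ], fraction_index = 1L),
    dplyr::mutate(br[1:2, ], fraction_index = 2L)
  )
  ts2 <- timing_summary(br2)
  expect_equal(ts2$two_sigma[ts2$level == "field"], c(0, 0))
  expect_equal(ts2$two_sigma[ts2$level == "plan"], 0)

  # mean and sd against brute force on random data
  set.seed(5)
  times <- rnorm(12, 40, 1)
  br3 <- tibble::tibble(field_id = "F01", fraction_index = 1:12,
                        drill_total = times, spot_switch_total = 0,
                        energy_switch_total = 0, interlock_total = 0,
                        delivery_time = times, had_interlock = FALSE)
  ts3 <- timing_summary(br3)
  frow <- ts3[ts3$level == "field", ]
  expect_equal(frow$mean_delivery_time, sum(times) / 12, tolerance = 1e-12)
  expect_equal(frow$two_sigma, 2 * bf_corrected_sd(times), tolerance = 1e-12)
})
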