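geo <- machine_geometry()

test_that("a zero-amplitude error model reproduces the plan bit-exactly", {
  plan <- tiny_plan(2, c(0, 180), layers = 3, spots = 15)
  fr <- simulate_fraction(plan, geo, error_model(rng_seed = 9), 1)
  key <- c("field_id", "layer_index", "spot_index")
  joined <- dplyr::inner_join(fr$spots, plan, by = key,
                              suffix = c("_log", "_plan"))
  expect_identical(joined$x_mm_log, joined$x_mm_plan)
  expect_identical(joined$y_mm_log, joined$y_mm_plan)
  expect_identical(joined$mu_log, joined$mu_plan)
  # deterministic timing: total in-field time = drill + switch intervals
  tm <- decompose_timing(fr)
  err <- error_model()
  expected_drill <- sum(round(err$drill_time_per_mu * fr$spots$mu * 1000)) / 1e6
  expect_equal(sum(tm$drill_total), expected_drill, tolerance = 1e-9)
  n_gaps <- nrow(fr$spots) - 2 * 3  # per field: n - n_layers within-layer gaps
  expect_equal(sum(tm$spot_switch_total),
               n_gaps * err$spot_switch_time_ms / 1000, tolerance = 1e-9)
  expect_equal(sum(tm$energy_switch_total), 2 * 2 * err$energy_switch_time_s,
               tolerance = 1e-9)
})

test_that("simulation is reproducible and fractions are independent streams", {
  plan <- tiny_plan(spots = 10, layers = 2)
  err <- error_model(position_noise_sd = 0.15, mu_noise_sd = 1e-3,
                     rng_seed = 4)
  a <- simulate_fraction(plan, geo, err, 2)
  b <- simulate_fraction(plan, geo, err, 2)
  expect_identical(a$spots, b$spots)
  expect_identical(a$events, b$events)
  # a different fraction index gives different noise
  c <- simulate_fraction(plan, geo, err, 3)
  expect_false(identical(a$spots$x_mm, c$spots$x_mm))
  # simulating fraction 5 does not depend on whether 1..4 were simulated
  d <- simulate_course(plan, geo, err, 5)[[2]]
  expect_identical(a$spots, d$spots)
})

test_that("empirical spot deviations converge to the configured model", {
  plan <- generate_plan(1, 90, layers_per_field = 2, spots_per_layer = 50,
                        target_radius = 30, rng_seed = 1)
  err <- error_model(x_offset_amplitude = 0.5, position_noise_sd = 0.2,
                     rng_seed = 8)
  frs <- simulate_course(plan, geo, err, 200)
  st <- expect_spot_stats(plan, frs)
  # systematic x offset at gantry 90 with the sine profile is -0.5 mm
  expect_equal(mean(st$mu_x), -0.5, tolerance = 0.05 * 0.5)
  # per-spot sd converges to the injected noise sd within 5%
  expect_equal(mean(st$sigma_x), 0.2, tolerance = 0.05 * 0.2)
  expect_equal(mean(st$sigma_y), 0.2, tolerance = 0.05 * 0.2)
})

test_that("high-MU field-edge spots are less reproducible than interior spots", {
  plan <- generate_plan(1, 90, layers_per_field = 1, spots_per_layer = 80,
                        target_radius = 30, rng_seed = 3)
  err <- error_model(position_noise_sd = 0.15,
                     edge_highmu_noise_multiplier = 2.5,
                     highmu_threshold = stats::median(plan$mu),
                     rng_seed = 12)
  frs <- simulate_course(plan, geo, err, 200)
  st <- expect_spot_stats(plan, frs)
  pitch <- attr(plan, "spot_spacing")
  edge <- lfqa:::edge_spots(plan$x_mm, plan$y_mm, pitch)
  hot <- edge & plan$mu >= stats::median(plan$mu)
  cold <- !edge & plan$mu < stats::median(plan$mu)
  expect_gt(min(nrow(st[hot, ]), nrow(st[cold, ])), 5)
  expect_gt(mean(st$sigma_x[hot]), 2 * mean(st$sigma_x[cold]))
  expect_gt(mean(st$sigma_y[hot]), 2 * mean(st$sigma_y[cold]))
})

test_that("interlock probability one yields an interlock pair in every field", {
  plan <- tiny_plan(2, c(10, 200), layers = 2, spots = 8)
  err <- error_model(interlock_probability_per_field = 1, rng_seed = 2)
  fr <- simulate_fraction(plan, geo, err, 1)
  for (fid in unique(fr$events$field_id)) {
    ev <- fr$events[fr$events$field_id == fid, ]
    expect_equal(sum(ev$kind == "INTERLOCK_START"), 1)
    expect_equal(sum(ev$kind == "INTERLOCK_END"), 1)
  }
  tm <- decompose_timing(fr)
  expect_true(all(tm$had_interlock))
  expect_true(all(tm$interlock_total > 0))
})

test_that("row offsets are systematic: identical across fractions", {
  plan <- tiny_plan(spots = 30, layers = 1)
  err <- error_model(y_row_offset = 0.3, rng_seed = 6)
  f1 <- simulate_fraction(plan, geo, err, 1)
  f9 <- simulate_fraction(plan, geo, err, 9)
  expect_identical(f1$spots$y_mm, f9$spots$y_mm)
  expect_true(any(f1$spots$y_mm != plan$y_mm))
  # spots on the same scan row share one offset
  dev <- f1$spots$y_mm - plan$y_mm
  per_row <- tapply(dev, plan$y_mm, function(v) diff(range(v)))
  expect_true(all(per_row < 1e-12))
})
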