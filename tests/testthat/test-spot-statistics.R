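test_that("accuracy, reproducibility and distance match their definitions", {
  expect_equal(suppressWarnings(spot_accuracy(c(1.0, 1.2, 0.8), 0.9)), 0.1)
  expect_equal(suppressWarnings(spot_accuracy(rep(2.5, 5), 2.5)), 0)
  expect_equal(suppressWarnings(spot_reproducibility(c(1, 2, 3))), 1.0)
  expect_equal(suppressWarnings(spot_reproducibility(rep(7, 4))), 0)
  expect_equal(spot_distance_accuracy(3, 4, 0, 0), 5.0)
  # opposite deviations: mean distance 1 while the mean deviation is 0
  expect_equal(spot_distance_accuracy(c(1, -1), c(0, 0), 0, 0), 1.0)
  expect_error(suppressWarnings(spot_accuracy(numeric(0), 1)),
               class = "lfqa_invalid_data")
  expect_error(suppressWarnings(spot_reproducibility(3)),
               class = "lfqa_invalid_data")
  expect_warning(spot_accuracy(c(1, 2), 1), class = "lfqa_few_fractions")
})

test_that("statistics agree with brute-force oracles on random data", {
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(2:40, 1)
    logged <- rnorm(n, sd = runif(1, 0.1, 5))
    planned <- rnorm(1)
    expect_equal(suppressWarnings(spot_accuracy(logged, planned)),
                 bf_mean_deviation(logged, planned), tolerance = 1e-12)
    expect_equal(suppressWarnings(spot_reproducibility(logged)),
                 bf_corrected_sd(logged), tolerance = 1e-12)
    xl <- rnorm(n); yl <- rnorm(n)
    expect_equal(spot_distance_accuracy(xl, yl, 0.3, -0.2),
                 bf_mean_distance(xl, yl, 0.3, -0.2), tolerance = 1e-12)
  }
})

test_that("sigma is shift invariant and mu shifts with the data", {
  set.seed(1)
  v <- rnorm(20)
  shift <- 3.7
  expect_equal(suppressWarnings(spot_reproducibility(v + shift)),
               suppressWarnings(spot_reproducibility(v)), tolerance = 1e-12)
  expect_equal(suppressWarnings(spot_accuracy(v + shift, 0)),
               suppressWarnings(spot_accuracy(v, 0)) + shift,
               tolerance = 1e-12)
})

test_that("mean distance dominates the norm of the mean deviation (Jensen)", {
  plan <- tiny_plan(spots = 40, layers = 2)
  err <- error_model(x_offset_amplitude = 0.3, position_noise_sd = 0.25,
                     rng_seed = 3)
  st <- expect_spot_stats(plan, simulate_course(plan, machine_geometry(),
                                                err, 10))
  expect_true(all(st$mean_distance >= st$distance_of_means - 1e-12))
})

test_that("aborted fractions are dropped from the statistics", {
  plan <- tiny_plan(spots = 10, layers = 3)
  geo <- machine_geometry()
  err <- error_model(position_noise_sd = 0.1, rng_seed = 5)
  frs <- simulate_course(plan, geo, err, 6)
  frs[[4]] <- abort_fraction(frs[[4]], "F01", after_layers = 1)
  st <- expect_spot_stats(plan, frs)
  expect_true(all(st$n_fractions == 5))
})

test_that("aggregation follows the mean (worst) convention and the quartiles", {
  stats <- tibble::tibble(
    plan_id = "p", field_id = "F01", gantry_angle = 90,
    layer_index = 0L, spot_index = 0:2,
    n_fractions = 15L,
    mu_x = c(-1.4, 0.0, 0.2), mu_y = 0, mu_mu = 0,
    sigma_x = 0.1, sigma_y = 0.1, sigma_mu = 0.001,
    mean_distance = 0.3, distance_of_means = 0.1
  )
  agg <- aggregate_spot_statistics(stats, "plan")
  row <- agg[agg$quantity == "mu_x", ]
  expect_equal(row$mean, -0.4)
  expect_equal(row$worst, -1.4)

  single <- aggregate_spot_statistics(stats[1, ], "plan")
  srow <- single[single$quantity == "mu_x", ]
  expect_equal(srow$mean, -1.4)
  expect_equal(srow$median, -1.4)
  expect_equal(srow$worst, -1.4)
})

test_that("distribution summaries match a brute-force quantile computation", {
  set.seed(9)
  for (rep in 1:10) {
    x <- rnorm(sample(c(5, 57, 1000), 1), sd = runif(1, 0.5, 3))
    ds <- distribution_summary(x)
    bf <- bf_distribution_summary(x)
    expect_equal(ds$median, bf$median, tolerance = 1e-12)
    expect_equal(ds$q1, bf$q1, tolerance = 1e-12)
    expect_equal(ds$q3, bf$q3, tolerance = 1e-12)
    expect_equal(ds$whisker_low, bf$whisker_low)
    expect_equal(ds$whisker_high, bf$whisker_high)
  }
})

test_that("grouping by gantry angle pools spots across fields at one angle", {
  plan <- generate_plan(3, c(90, 90, 270), 1, 10, 20, rng_seed = 2)
  err <- error_model(x_offset_amplitude = 0.5, position_noise_sd = 0.05,
                     rng_seed = 7)
  st <- expect_spot_stats(plan, simulate_course(plan, machine_geometry(),
                                                err, 8))
  agg <- aggregate_spot_statistics(st, "gantry_angle")
  mu_x_rows <- agg[agg$quantity == "mu_x", ]
  expect_equal(sort(mu_x_rows$gantry_angle), c(90, 270))
  expect_equal(mu_x_rows$n[mu_x_rows$gantry_angle == 90], 20)
  # sine profile: negative offset at 90 deg, positive at 270 deg
  expect_lt(mu_x_rows$mean[mu_x_rows$gantry_angle == 90], -0.3)
  expect_gt(mu_x_rows$mean[mu_x_rows$gantry_angle == 270], 0.3)
})
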