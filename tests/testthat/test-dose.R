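grid20 <- dose_grid(c(20, 20, 20), 3)

test_that("the dose engine is linear in MU and deterministic", {
  plan <- tiny_plan(spots = 25, layers = 2)
  d1 <- reconstruct_dose(plan, grid20)
  d2 <- reconstruct_dose(plan, grid20)
  expect_identical(d1$values, d2$values)
  plan2 <- dplyr::mutate(plan, mu = 2 * mu)
  d2x <- reconstruct_dose(plan2, grid20)
  expect_identical(d2x$values, 2 * d1$values)
})

test_that("a single spot produces a transverse Gaussian centered on it", {
  spot <- tibble::tibble(gantry_angle = 0, energy_mev = 100,
                         x_mm = 4.5, y_mm = -6, mu = 1)
  g <- dose_grid(c(31, 31, 31), 2)
  d <- reconstruct_dose(spot, g, phantom_entry_depth = 40)
  peak <- which(d$values == max(d$values), arr.ind = TRUE)[1, ]
  xs <- g$origin[1] + (seq_len(g$shape[1]) - 1) * g$spacing[1]
  ys <- g$origin[2] + (seq_len(g$shape[2]) - 1) * g$spacing[2]
  prof_x <- d$values[, peak[2], peak[3]]
  prof_y <- d$values[peak[1], , peak[3]]
  fit_center <- function(pos, w) sum(pos * w) / sum(w)
  expect_equal(fit_center(xs, prof_x), 4.5, tolerance = 0.1 * g$spacing[1])
  expect_equal(fit_center(ys, prof_y), -6, tolerance = 0.1 * g$spacing[2])
})

test_that("integral dose is proportional to total MU", {
  plan <- tiny_plan(spots = 30, layers = 3, radius = 20)
  grid <- dose_grid(c(50, 50, 50), 3)
  d <- reconstruct_dose(plan, grid)
  expect_equal(integral_dose(d), sum(plan$mu), tolerance = 0.01)
})

test_that("translating all spots translates the transverse dose pattern", {
  plan <- tiny_plan(1, 0, layers = 1, spots = 12, radius = 15)
  g <- dose_grid(c(40, 40, 40), 2)
  d0 <- reconstruct_dose(plan, g, phantom_entry_depth = 40)
  shifted <- dplyr::mutate(plan, x_mm = x_mm + g$spacing[1],
                           y_mm = y_mm + g$spacing[2])
  d1 <- reconstruct_dose(shifted, g, phantom_entry_depth = 40)
  # gantry 0: beam along -z, BEV x -> +room x, BEV y -> +room y
  interior <- 2:39
  expect_equal(d1$values[interior, interior, ],
               d0$values[interior - 1, interior - 1, ], tolerance = 1e-9)
})

test_that("spots outside the grid are skipped with a warning and counted", {
  spots <- tibble::tibble(gantry_angle = 0, energy_mev = 100,
                          x_mm = c(0, 500), y_mm = 0, mu = 1)
  expect_warning(d <- reconstruct_dose(spots, grid20),
                 class = "lfqa_geometry_warning")
  expect_equal(attr(d, "n_skipped"), 1L)
})

test_that("log-file plans replace delivered parameters and nothing else", {
  plan <- tiny_plan(spots = 15, layers = 2)
  geo <- machine_geometry()
  fr0 <- simulate_fraction(plan, geo, error_model(rng_seed = 1), 1)
  expect_equal(as.data.frame(build_logfile_plan(plan, fr0)[, names(plan)]),
               as.data.frame(plan))
  err <- error_model(mu_noise_sd = 1e-3, rng_seed = 1)
  fr1 <- simulate_fraction(plan, geo, err, 1)
  lp <- build_logfile_plan(plan, fr1)
  expect_identical(lp$x_mm, plan$x_mm)
  expect_identical(lp$y_mm, plan$y_mm)
  expect_false(identical(lp$mu, plan$mu))
  expect_identical(lp$energy_mev, plan$energy_mev)
  # known injected offsets propagate exactly
  err2 <- error_model(x_offset_amplitude = 0.5, rng_seed = 1)
  fr2 <- simulate_fraction(plan, geo, err2, 1)
  lp2 <- build_logfile_plan(plan, fr2)
  expect_equal(lp2$x_mm - plan$x_mm, rep(-0.5, nrow(plan)), tolerance = 1e-12)
  # a missing spot in a non-aborted fraction is an integrity error
  fr_broken <- fr1
  fr_broken$spots <- fr_broken$spots[-3, ]
  expect_error(build_logfile_plan(plan, fr_broken),
               class = "lfqa_integrity_error")
})

test_that("dose grids round-trip through the text format", {
  d <- random_dose(c(6, 5, 4), spacing = c(2, 3, 4), seed = 3)
  path <- withr::local_tempfile()
  write_dose_grid(d, path)
  back <- read_dose_grid(path)
  expect_equal(back$values, d$values, tolerance = 1e-15)
  expect_equal(back$origin, d$origin)
  expect_equal(back$spacing, d$spacing)
})
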