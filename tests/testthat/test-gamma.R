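test_that("identity comparison passes every voxel with gamma zero", {
  d <- random_dose(c(12, 12, 12), seed = 1)
  res <- gamma_index(d, d, gamma_criteria(1, 1), keep_gamma_map = TRUE)
  expect_equal(res$pass_rate, 100)
  evaluated <- !is.na(res$gamma_map)
  expect_equal(res$n_evaluated, sum(evaluated))
  expect_true(all(res$gamma_map[evaluated] == 0))
  # cutoff: only voxels at or above 10% of the reference max are evaluated
  expect_equal(sum(d$values >= 0.1 * max(d$values)), res$n_evaluated)
})

test_that("a pure dose difference at the criterion sits on the pass boundary", {
  # uniform dose: no spatial gradient can help, gamma = dose term exactly
  # (values chosen binary-exact so the boundary is hit without rounding)
  ref <- dose_grid(c(7, 7, 7), 3, values = array(1, c(7, 7, 7)))
  ev <- dose_grid(c(7, 7, 7), 3, values = array(1.25, c(7, 7, 7)))
  res <- gamma_index(ref, ev, gamma_criteria(25, 1, normalization = 1),
                     keep_gamma_map = TRUE)
  expect_identical(max(res$gamma_map, na.rm = TRUE), 1)
  expect_equal(res$pass_rate, 100)  # gamma <= 1 is inclusive
  res2 <- gamma_index(ref, ev, gamma_criteria(24, 1, normalization = 1))
  expect_equal(res2$pass_rate, 0)
})

test_that("optimized gamma equals the dense brute-force oracle per voxel", {
  for (seed in 1:6) {
    ref <- random_dose(c(10, 10, 10), seed = seed)
    ev <- perturb_dose(ref, amplitude = 0.03, seed = seed + 100)
    crit <- gamma_criteria(2, 2, search_radius_factor = 1.5)
    res <- gamma_index(ref, ev, crit, keep_gamma_map = TRUE)
    orc <- oracle_gamma(ref, ev, 2, 2, search_radius_factor = 1.5)
    expect_equal(res$n_evaluated, orc$n_evaluated)
    expect_equal(res$gamma_map, orc$gamma, tolerance = 1e-12)
    expect_identical(res$gamma_map <= 1, orc$gamma <= 1)
    expect_equal(res$pass_rate, orc$pass_rate, tolerance = 1e-12)
  }
})

test_that("early exit changes no gamma value versus the uncapped search", {
  ref <- random_dose(c(10, 10, 10), seed = 5)
  ev <- perturb_dose(ref, amplitude = 0.05, seed = 50)
  crit <- gamma_criteria(1, 1, search_radius_factor = 1.5)
  norm <- max(ref$values)
  fast <- lfqa:::cpp_gamma(as.numeric(ref$values), ref$shape, ref$origin,
                           ref$spacing, as.numeric(ev$values), ev$shape,
                           ev$origin, ev$spacing, 1, 1, 0.1, 0.1, norm,
                           1.5, TRUE)
  dense <- lfqa:::cpp_gamma(as.numeric(ref$values), ref$shape, ref$origin,
                            ref$spacing, as.numeric(ev$values), ev$shape,
                            ev$origin, ev$spacing, 1, 1, 0.1, 0.1, norm,
                            1.5, FALSE)
  expect_lt(max(abs(fast$gamma - dense$gamma), na.rm = TRUE), 1e-9)
})

test_that("gamma is invariant under joint rescaling of doses and normalization", {
  ref <- random_dose(c(9, 9, 9), seed = 2)
  ev <- perturb_dose(ref, amplitude = 0.04, seed = 20)
  c1 <- gamma_criteria(2, 2, normalization = max(ref$values))
  r1 <- gamma_index(ref, ev, c1, keep_gamma_map = TRUE)
  scale <- 7.3
  ref2 <- dose_grid(ref$shape, ref$spacing, ref$origin, scale * ref$values)
  ev2 <- dose_grid(ev$shape, ev$spacing, ev$origin, scale * ev$values)
  c2 <- gamma_criteria(2, 2, normalization = scale * max(ref$values))
  r2 <- gamma_index(ref2, ev2, c2, keep_gamma_map = TRUE)
  expect_equal(r2$gamma_map, r1$gamma_map, tolerance = 1e-9)
})

test_that("tightening criteria never increases the pass rate", {
  for (seed in c(3, 13, 23)) {
    ref <- random_dose(c(10, 10, 10), seed = seed)
    ev <- perturb_dose(ref, amplitude = 0.04, seed = seed + 7)
    g11 <- gamma_index(ref, ev, gamma_criteria(1, 1))$pass_rate
    g22 <- gamma_index(ref, ev, gamma_criteria(2, 2))$pass_rate
    expect_lte(g11, g22)
  }
})

test_that("gamma series fix the normalization from the reference", {
  ref <- random_dose(c(8, 8, 8), seed = 4)
  evs <- list(ref, perturb_dose(ref, 0.02, 41), perturb_dose(ref, 0.08, 42))
  rates <- gamma_series(ref, evs, gamma_criteria(1, 1))
  expect_equal(rates[1], 100)
  expect_lte(rates[3], rates[2])
})

test_that("degenerate gamma inputs are rejected", {
  d <- random_dose(c(6, 6, 6), seed = 1)
  zero <- dose_grid(c(6, 6, 6), 3, values = array(0, c(6, 6, 6)))
  expect_error(gamma_index(zero, d, gamma_criteria(1, 1)),
               class = "lfqa_invalid_argument")
  expect_error(gamma_series(d, list(), gamma_criteria(1, 1)),
               class = "lfqa_invalid_argument")
})
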