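# Small fixtures built in code.

tiny_plan <- function(n_fields = 1, angles = 90, layers = 2, spots = 20,
                      radius = 30, seed = 7, ...) {
  generate_plan(n_fields, angles, layers, spots, radius, rng_seed = seed, ...)
}

# A smooth, strictly positive random dose grid (separable bump times noise),
# so gamma comparisons see realistic gradients rather than white noise.
random_dose <- function(shape = c(10, 10, 10), spacing = 3, seed = 1,
                        noise = 0.05) {
  set.seed(seed)
  ax <- lapply(shape, function(n) {
    c0 <- runif(1, n / 3, 2 * n / 3)
    w <- runif(1, n / 5, n / 2)
    exp(-((seq_len(n) - c0)^2) / (2 * w^2))
  })
  base <- outer(outer(ax[[1]], ax[[2]]), ax[[3]])
  vals <- base * (1 + noise * array(rnorm(prod(shape)), dim = shape))
  dose_grid(shape, spacing, values = pmax(vals, 0))
}

# Perturb a dose grid smoothly: scale plus a low-frequency multiplicative
# field, emulating a slightly different delivered dose.
perturb_dose <- function(grid, amplitude = 0.02, seed = 2) {
  set.seed(seed)
  sh <- grid$shape
  ax <- lapply(sh, function(n) 1 + amplitude * sin(seq_len(n) / n * 2 * pi +
                                                     runif(1, 0, 2 * pi)))
  mod <- outer(outer(ax[[1]], ax[[2]]), ax[[3]])
  dose_grid(sh, grid$spacing, grid$origin, grid$values * mod)
}

expect_spot_stats <- function(plan, fractions) {
  suppressWarnings(spot_statistics(plan, fractions))
}
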