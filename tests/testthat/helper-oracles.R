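# Independent brute-force oracles. These deliberately share no code with the
# package: plain loops and textbook formulas, used to pin down the package's
# optimized implementations.

bf_mean_deviation <- function(logged, planned) {
  s <- 0
  for (v in logged) s <- s + (v - planned)
  s / length(logged)
}

bf_corrected_sd <- function(values) {
  n <- length(values)
  m <- 0
  for (v in values) m <- m + v
  m <- m / n
  s2 <- 0
  for (v in values) s2 <- s2 + (v - m)^2
  sqrt(s2 / (n - 1))
}

bf_mean_distance <- function(xl, yl, xp, yp) {
  s <- 0
  for (i in seq_along(xl)) {
    s <- s + sqrt((xl[i] - xp)^2 + (yl[i] - yp)^2)
  }
  s / length(xl)
}

bf_lambda <- function(mu, d, D) {
  num <- 0
  den <- 0
  for (i in seq_along(mu)) {
    den <- den + mu[i]
    if (d[i] < D) num <- num + mu[i]
  }
  100 * num / den
}

bf_pearson <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n
  mb <- sum(b) / n
  sab <- 0; saa <- 0; sbb <- 0
  for (i in seq_len(n)) {
    sab <- sab + (a[i] - ma) * (b[i] - mb)
    saa <- saa + (a[i] - ma)^2
    sbb <- sbb + (b[i] - mb)^2
  }
  sab / sqrt(saa * sbb)
}

bf_distribution_summary <- function(x) {
  # quartiles by the linear-interpolation convention, from first principles
  xs <- sort(x)
  n <- length(xs)
  qlin <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    xs[lo] + (h - lo) * (xs[hi] - xs[lo])
  }
  q1 <- qlin(0.25); med <- qlin(0.5); q3 <- qlin(0.75)
  iqr <- q3 - q1
  list(median = med, q1 = q1, q3 = q3,
       whisker_low = min(xs[xs >= q1 - 1.5 * iqr]),
       whisker_high = max(xs[xs <= q3 + 1.5 * iqr]))
}

# Trilinear interpolation on a dose_grid, vectorized over query points.
# Returns list(ok, value).
oracle_trilinear <- function(grid, x, y, z) {
  dim3 <- grid$shape
  gx <- (x - grid$origin[1]) / grid$spacing[1]
  gy <- (y - grid$origin[2]) / grid$spacing[2]
  gz <- (z - grid$origin[3]) / grid$spacing[3]
  ok <- gx >= 0 & gx <= dim3[1] - 1 &
    gy >= 0 & gy <= dim3[2] - 1 &
    gz >= 0 & gz <= dim3[3] - 1
  i0 <- pmin(pmax(floor(gx), 0), dim3[1] - 2)
  j0 <- pmin(pmax(floor(gy), 0), dim3[2] - 2)
  k0 <- pmin(pmax(floor(gz), 0), dim3[3] - 2)
  fx <- gx - i0; fy <- gy - j0; fz <- gz - k0
  vals <- as.numeric(grid$values)
  nx <- dim3[1]; ny <- dim3[2]
  acc <- numeric(length(x))
  for (c in 0:7) {
    ax <- bitwAnd(c, 1L)
    ay <- bitwAnd(bitwShiftR(c, 1L), 1L)
    az <- bitwAnd(bitwShiftR(c, 2L), 1L)
    w <- (if (ax) fx else 1 - fx) * (if (ay) fy else 1 - fy) *
      (if (az) fz else 1 - fz)
    idx <- (i0 + ax) + nx * ((j0 + ay) + ny * (k0 + az)) + 1
    acc <- acc + ifelse(w == 0, 0, w * vals[pmin(pmax(idx, 1), length(vals))])
  }
  list(ok = ok, value = acc)
}

# Dense exhaustive 3D gamma: every lattice offset is visited for every
# above-cutoff reference voxel, no early exit, no ordering.
oracle_gamma <- function(reference, evaluation, dose_percent, dta,
                         cutoff_fraction = 0.10, interp_fraction = 0.10,
                         normalization = max(reference$values),
                         search_radius_factor = 1.5) {
  step <- interp_fraction * dta
  m <- floor(search_radius_factor * dta / step + 1e-9)
  offs <- expand.grid(i = -m:m, j = -m:m, k = -m:m)
  dx <- offs$i * step; dy <- offs$j * step; dz <- offs$k * step
  d2 <- dx^2 + dy^2 + dz^2
  keep <- d2 <= (search_radius_factor * dta)^2 * (1 + 1e-12)
  dx <- dx[keep]; dy <- dy[keep]; dz <- dz[keep]
  dist2norm <- d2[keep] / (dta * dta)
  denom <- dose_percent / 100 * normalization
  cutoff <- cutoff_fraction * normalization
  sh <- reference$shape
  gamma <- array(NA_real_, dim = sh)
  for (k in seq_len(sh[3])) {
    for (j in seq_len(sh[2])) {
      for (i in seq_len(sh[1])) {
        dr <- reference$values[i, j, k]
        if (dr < cutoff) next
        px <- reference$origin[1] + (i - 1) * reference$spacing[1]
        py <- reference$origin[2] + (j - 1) * reference$spacing[2]
        pz <- reference$origin[3] + (k - 1) * reference$spacing[3]
        tri <- oracle_trilinear(evaluation, px + dx, py + dy, pz + dz)
        dd <- (tri$value - dr) / denom
        g2 <- dist2norm + dd * dd
        g2 <- g2[tri$ok]
        gamma[i, j, k] <- if (length(g2) == 0) Inf else sqrt(min(g2))
      }
    }
  }
  n_eval <- sum(!is.na(gamma))
  list(gamma = gamma,
       pass_rate = 100 * sum(gamma <= 1, na.rm = TRUE) / n_eval,
       n_evaluated = n_eval)
}
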