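#' 3D dose grid
#'
#' A regular 3D scalar dose grid in the fixed (room) frame. `origin` is the
#' center of the first voxel; voxel `(i, j, k)` (1-based) sits at
#' `origin + (i-1, j-1, k-1) * spacing`.
#'
#' @param shape Integer vector of length 3: voxels per axis.
#' @param spacing Voxel size per axis (mm); scalar or length 3. Default 3 mm
#'   isotropic, the voxel length used for dose reconstruction.
#' @param origin Position of the first voxel center (mm); defaults to
#'   centering the grid on the isocenter.
#' @param values Optional array of doses (defaults to zeros).
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(shape, spacing = 3, origin = NULL, values = NULL) {
  shape <- as.integer(rep(shape, length.out = 3))
  spacing <- rep(as.numeric(spacing), length.out = 3)
  if (any(spacing <= 0)) stop_lfqa("spacing must be > 0", "lfqa_invalid_argument")
  if (is.null(origin)) origin <- -(shape - 1) * spacing / 2
  origin <- rep(as.numeric(origin), length.out = 3)
  if (is.null(values)) {
    values <- array(0, dim = shape)
  } else {
    values <- array(as.numeric(values), dim = shape)
  }
  structure(list(values = values, origin = origin, spacing = spacing,
                 shape = shape),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %s voxels, spacing %s mm, max dose %.4g\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              max(x$values)))
  invisible(x)
}

# Voxel center coordinates, one row per voxel in array (column-major) order.
grid_coords <- function(grid) {
  ax <- lapply(1:3, function(a) grid$origin[a] + (seq_len(grid$shape[a]) - 1) *
                 grid$spacing[a])
  cbind(
    rep(ax[[1]], times = grid$shape[2] * grid$shape[3]),
    rep(rep(ax[[2]], each = grid$shape[1]), times = grid$shape[3]),
    rep(ax[[3]], each = grid$shape[1] * grid$shape[2])
  )
}

#' Reconstruct a 3D dose distribution from a spot list
#'
#' Superposes analytic pencil-beam kernels for every spot onto a homogeneous
#' water grid: each spot deposits `mu` times a normalized depth-dose curve
#' with a Bragg-like peak at the range `R(E)` along its field axis, times a
#' normalized 2D Gaussian in the transverse plane centered at the spot's
#' `(x, y)` with `sigma(z) = sigma0 + sigma_growth * z`. The field axis is
#' the beam direction rotated by the gantry angle about the fixed-frame y
#' axis; spot axes within a field are parallel (divergence is handled
#' upstream by the isocenter projection, not in the dose engine). Dose is
#' additive over fields, linear in MU and fully deterministic. This engine
#' deliberately trades physical fidelity for a faithful, smooth sensitivity
#' of dose to spot position and MU perturbations.
#'
#' Pass the plan itself for the planned dose, or [build_logfile_plan()]
#' output for a reconstructed fraction dose.
#'
#' @param spots Tibble with columns `gantry_angle`, `energy_mev`, `x_mm`,
#'   `y_mm`, `mu` (an `lfqa_plan` works as is).
#' @param grid A [dose_grid()] defining origin/spacing/shape (its values are
#'   ignored).
#' @param beam A [beam_model()].
#' @param phantom_entry_depth Water-equivalent depth of the isocenter below
#'   the phantom surface (mm): a voxel's depth is
#'   `phantom_entry_depth + <position, beam direction>`. The default puts the
#'   surface 60 mm upstream of the isocenter so the default energy range
#'   (90-110 MeV, ranges 63-91 mm) peaks inside the default grid.
#' @param lateral_cutoff_sigmas Lateral truncation of the Gaussian kernel in
#'   units of sigma.
#' @return A `dose_grid` with the reconstructed dose. The number of skipped
#'   spots (axis outside the grid) is reported via a warning and the
#'   `n_skipped` attribute.
#' @export
reconstruct_dose <- function(spots, grid, beam = beam_model(),
                             phantom_entry_depth = 60,
                             lateral_cutoff_sigmas = 4) {
  if (nrow(spots) == 0) stop_lfqa("no spots to reconstruct", "lfqa_invalid_data")
  coords <- grid_coords(grid)
  dose <- numeric(nrow(coords))
  n_skipped <- 0L
  for (angle in unique(spots$gantry_angle)) {
    fsp <- spots[spots$gantry_angle == angle, ]
    th <- angle * pi / 180
    d_axis <- c(sin(th), 0, -cos(th))   # beam direction
    u_axis <- c(cos(th), 0, sin(th))    # BEV x (fast scan)
    # BEV y (slow scan) is the fixed-frame y axis
    u <- coords %*% u_axis
    v <- coords[, 2]
    depth <- phantom_entry_depth + coords %*% d_axis
    sig_max <- beam$sigma0 + beam$sigma_growth * max(depth, 0)
    margin <- lateral_cutoff_sigmas * sig_max
    inside <- fsp$x_mm >= min(u) - margin & fsp$x_mm <= max(u) + margin &
      fsp$y_mm >= min(v) - margin & fsp$y_mm <= max(v) + margin
    n_skipped <- n_skipped + sum(!inside)
    fsp <- fsp[inside, ]
    if (nrow(fsp) == 0) next
    cpp_superpose(dose, as.numeric(u), as.numeric(v), as.numeric(depth),
                  fsp$x_mm, fsp$y_mm, fsp$mu,
                  beam_range(fsp$energy_mev, beam),
                  beam$bragg_width, beam$sigma0, beam$sigma_growth,
                  lateral_cutoff_sigmas)
  }
  if (n_skipped > 0) {
    warn(sprintf("%d spot(s) fell outside the dose grid and were skipped",
                 n_skipped), class = "lfqa_geometry_warning")
  }
  out <- dose_grid(grid$shape, grid$spacing, grid$origin, dose)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Build a log-file plan from a delivered fraction
#'
#' Overwrites the planned spot parameters (x, y, MU) with the values logged
#' in the given fraction, keeping energies and gantry angles untouched. The
#' result feeds [reconstruct_dose()] to obtain the fraction's reconstructed
#' dose.
#'
#' @param plan An `lfqa_plan`.
#' @param fraction A `fraction_log`.
#' @return An `lfqa_plan` with logged positions and MU. For an aborted
#'   fraction only the delivered spots are returned (a partial plan).
#' @export
build_logfile_plan <- function(plan, fraction) {
  joined <- dplyr::inner_join(
    plan, fraction$spots[, c(spot_key_cols, "x_mm", "y_mm", "mu")],
    by = spot_key_cols, suffix = c("_plan", "_log")
  )
  if (!fraction$aborted && nrow(joined) < nrow(plan)) {
    stop_lfqa("non-aborted fraction is missing planned spots",
              "lfqa_integrity_error")
  }
  out <- joined |>
    dplyr::transmute(
      plan_id = .data$plan_id, field_id = .data$field_id,
      gantry_angle = .data$gantry_angle, layer_index = .data$layer_index,
      energy_mev = .data$energy_mev, spot_index = .data$spot_index,
      x_mm = .data$x_mm_log, y_mm = .data$y_mm_log, mu = .data$mu_log
    )
  new_lfqa_plan(out, spot_spacing = attr(plan, "spot_spacing"))
}

#' Write / read a dose grid as text with a JSON sidecar
#'
#' Values are written one per line in array (column-major) order to `path`;
#' origin, spacing and shape go to `<path>.json`.
#'
#' @param grid A `dose_grid`.
#' @param path File path for the values.
#' @return The grid (writer, invisibly) or a `dose_grid` (reader).
#' @export
write_dose_grid <- function(grid, path) {
  jsonlite::write_json(
    list(origin = grid$origin, spacing = grid$spacing, shape = grid$shape),
    paste0(path, ".json"), auto_unbox = FALSE, digits = NA
  )
  writeLines(formatC(as.numeric(grid$values), digits = 17, format = "g"), path)
  invisible(grid)
}

#' @rdname write_dose_grid
#' @export
read_dose_grid <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- as.numeric(readLines(path))
  dose_grid(meta$shape, meta$spacing, meta$origin, vals)
}

#' Integral dose of a grid
#'
#' Sum of voxel doses times voxel volume, in MU-equivalent units of the
#' normalized kernel (so it approximates the total MU whose kernel mass lies
#' inside the grid).
#'
#' @param grid A `dose_grid`.
#' @return Scalar integral dose.
#' @export
integral_dose <- function(grid) {
  sum(grid$values) * prod(grid$spacing)
}
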