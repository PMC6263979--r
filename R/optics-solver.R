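#' Fluence field container
#'
#' Space- (and optionally time-) resolved fluence on a [cartesian_grid()].
#' Steady (time-integrated) solves carry J/cm^2 values; transient solves
#' carry W/cm^2 snapshots on `time_axis`.
#'
#' @param grid A [cartesian_grid()].
#' @param values 3-D array (steady) or 4-D array (transient, last axis
#'   time), all values >= 0.
#' @param time_axis Strictly increasing sample times in ns, or `NULL`.
#' @param mode `"steady"` or `"transient"`.
#' @param units Unit label for `values`.
#' @return A `fluence_field` object.
#' @export
fluence_field <- function(grid, values, time_axis = NULL,
                          mode = c("steady", "transient"),
                          units = if (is.null(time_axis)) "J/cm^2" else "W/cm^2") {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "cartesian_grid"))
  if (min(values) < -1e-12 * max(abs(values))) {
    stop("fluence values must be non-negative", call. = FALSE)
  }
  if (!is.null(time_axis) && any(diff(time_axis) <= 0)) {
    stop("`time_axis` must be strictly increasing", call. = FALSE)
  }
  structure(list(grid = grid, values = values, time_axis = time_axis,
                 mode = mode, units = units),
            class = "fluence_field")
}

#' @export
print.fluence_field <- function(x, ...) {
  cat(sprintf("<fluence_field: %s> %s cells, max %.4g %s\n", x$mode,
              paste(dim(x$values), collapse = " x "), max(x$values), x$units))
  invisible(x)
}

# trilinear interpolation of a 3-D array at physical points (mm)
interp3 <- function(grid, values, px, py, pz) {
  locate <- function(coord, p) {
    i <- findInterval(p, coord, all.inside = TRUE)
    f <- (p - coord[i]) / (coord[i + 1] - coord[i])
    list(i = i, f = pmin(1, pmax(0, f)))
  }
  lx <- locate(grid$x, px); ly <- locate(grid$y, py); lz <- locate(grid$z, pz)
  v <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) lx$f else 1 - lx$f) *
         (if (dy) ly$f else 1 - ly$f) *
         (if (dz) lz$f else 1 - lz$f)
    v <- v + w * values[cbind(lx$i + dx, ly$i + dy, lz$i + dz)]
  }
  v
}

#' Solve the pulsed-light diffusion equation
#'
#' Solves `(n/c) dphi/dt - div(D grad phi) + mu_a phi = P0` with
#' `D = 1/(3 (mu_s' + mu_a))` and the Robin condition
#' `-D grad(phi) . n = h phi` (coefficient from
#' [robin_boundary_coefficient()]) on all outer faces, for the dual-arm
#' source of [build_dual_arm_sources()].
#'
#' Steady mode drops the time derivative and uses the time-integrated
#' pulse energy as the source, returning fluence in J/cm^2; this is the
#' default for design sweeps since relative fluence at fixed positions is
#' identical for the time-integrated field.  Transient mode integrates
#' with unconditionally stable Crank-Nicolson steps (default
#' `dt = tau_p / 20`) and returns W/cm^2 snapshots; it is intended for
#' small grids feeding the PA generation chain.
#'
#' @param medium An [optical_medium()].
#' @param pulse A [pulse_profile()].
#' @param geom An [illumination_geometry()].
#' @param grid A [cartesian_grid()].  Spacing must resolve the transport
#'   mean free path (`spacing <= 5 * Z0`).
#' @param mode `"steady"` or `"transient"`.
#' @param t_end,dt Transient-mode time span and step (ns).
#' @param tol,maxit Conjugate-gradient relative tolerance and iteration cap
#'   for the steady solve.
#' @return A [fluence_field()].
#' @export
solve_fluence <- function(medium, pulse, geom, grid,
                          mode = c("steady", "transient"),
                          t_end = NULL, dt = NULL,
                          tol = 1e-8, maxit = 20000L) {
  mode <- match.arg(mode)
  stopifnot(inherits(medium, "optical_medium"), inherits(pulse, "pulse_profile"))
  z0_mm <- 10 * transport_mean_free_path(medium)
  if (grid$spacing > 5 * z0_mm) {
    stop("grid spacing does not resolve the transport mean free path",
         call. = FALSE)
  }
  musp_mm <- reduced_scattering(medium$mu_s, medium$g) / 10
  mua_mm <- medium$mu_a / 10
  D_mm <- 1 / (3 * (mua_mm + musp_mm))
  hb <- robin_boundary_coefficient(medium$n)
  # time-integral of the printed Gaussian source: mu_s' * Wp / pi per arm
  pulse_energy_scale <- musp_mm * pulse$Wp / pi

  if (mode == "steady") {
    src <- build_dual_arm_sources(geom, medium, grid,
                                  unit_scale = pulse_energy_scale)
    sol <- .diffusion_solve_cg(as.numeric(src$values),
                               grid$dim[1], grid$dim[2], grid$dim[3],
                               D_mm, mua_mm, grid$spacing, hb, tol, maxit)
    phi <- array(pmax(sol$phi, 0), dim = grid$dim) * 0.1  # mJ/mm^2 -> J/cm^2
    out <- fluence_field(grid, phi, mode = "steady")
    attr(out, "solver") <- list(iterations = sol$iterations,
                                relres = sol$relres,
                                source = src[c("footprint", "z_patch",
                                               "interval_at_z0")])
    return(out)
  }

  # transient Crank-Nicolson (small grids: assembles the sparse operator)
  if (is.null(dt)) dt <- pulse$tau_p / 20
  if (is.null(t_end)) t_end <- pulse$tau_center + 3 * pulse$tau_p
  times <- seq(0, t_end, by = dt)
  n_over_c <- medium$n / 299.792458  # ns per mm
  A <- diffusion_operator_matrix(grid, D_mm, mua_mm, hb)
  n <- prod(grid$dim)
  M <- Matrix::Diagonal(n, n_over_c / dt)
  lhs <- M + A / 2
  rhs_op <- M - A / 2
  fac <- Matrix::Cholesky(methods::as(lhs, "symmetricMatrix"))
  src <- build_dual_arm_sources(geom, medium, grid, unit_scale = 1)
  s_shape <- as.numeric(src$values)
  # mm-consistent source density: the printed prefactor carries mu_s' in
  # 1/cm; the grid works in mm
  p0 <- gaussian_pulse_power(times, medium, pulse) / 10
  phi <- numeric(n)
  snaps <- array(0, dim = c(grid$dim, length(times)))
  for (m in seq_along(times)[-1]) {
    b <- rhs_op %*% phi + s_shape * (p0[m - 1] + p0[m]) / 2
    phi <- as.numeric(Matrix::solve(fac, b))
    snaps[, , , m] <- pmax(array(phi, grid$dim), 0)
  }
  # mJ/(mm^2 ns) -> W/cm^2: 1 mJ/ns = 1e6 W; 1/mm^2 = 100/cm^2
  out <- fluence_field(grid, snaps * 1e8, time_axis = times, mode = "transient")
  out
}

# sparse symmetric operator for the transient solver (small grids only)
diffusion_operator_matrix <- function(grid, D_mm, mua_mm, hb) {
  nd <- grid$dim; h <- grid$spacing
  n <- prod(nd)
  w <- D_mm / h^2
  alpha <- hb * 2 * D_mm / (hb * h + 2 * D_mm)
  idx <- array(seq_len(n), dim = nd)
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  diag_v <- rep(mua_mm, n)
  for (ax in 1:3) {
    nax <- nd[ax]
    lo <- slice.index(idx, ax) > 1
    # off-diagonal to the "minus" neighbor along ax
    from <- idx[lo]
    shift <- c(1, nd[1], nd[1] * nd[2])[ax]
    to <- from - shift
    ii <- c(ii, from); jj <- c(jj, to); vv <- c(vv, rep(-w, length(from)))
    diag_v[from] <- diag_v[from] + w
    diag_v[to] <- diag_v[to] + w
    # Robin walls on both faces of this axis
    wall <- slice.index(idx, ax) == 1 | slice.index(idx, ax) == nax
    diag_v[idx[wall]] <- diag_v[idx[wall]] + alpha / h
  }
  Matrix::sparseMatrix(i = c(ii, jj, seq_len(n)), j = c(jj, ii, seq_len(n)),
                       x = c(vv, vv, diag_v), dims = c(n, n))
}

#' Fluence depth profile at the arm midline
#'
#' Samples a solved [fluence_field()] along the vertical line through the
#' midpoint between the two arms (x = 0, y = 0), from the surface down to
#' 20 mm, the standard observation line for illumination design sweeps.
#'
#' @param field A steady [fluence_field()].
#' @param depths Depths (mm) to sample; default every 0.25 mm to 20 mm.
#' @param lateral_midpoint `(x, y)` of the vertical line (mm), default
#'   `c(0, 0)`.
#' @return A tibble with columns `depth_mm` and `fluence`.
#' @export
fluence_depth_profile <- function(field, depths = seq(0.25, 20, by = 0.25),
                                  lateral_midpoint = c(0, 0)) {
  stopifnot(inherits(field, "fluence_field"))
  g <- field$grid
  if (abs(lateral_midpoint[1]) > g$extents[1] / 2 ||
      abs(lateral_midpoint[2]) > g$extents[2] / 2 ||
      any(depths < 0) || any(depths > g$extents[3])) {
    stop("observation line outside the grid", call. = FALSE)
  }
  vals <- field$values
  if (field$mode == "transient") {
    vals <- vals[, , , dim(vals)[4]]  # last snapshot
  }
  f <- interp3(g, vals, rep(lateral_midpoint[1], length(depths)),
               rep(lateral_midpoint[2], length(depths)), depths)
  tibble::tibble(depth_mm = depths, fluence = f)
}

#' Sample a steady fluence field at one midline depth
#'
#' @param field A [fluence_field()].
#' @param depth_mm Depth below the surface (mm).
#' @return Fluence value at (0, 0, depth).
#' @export
fluence_at_depth <- function(field, depth_mm) {
  fluence_depth_profile(field, depths = depth_mm)$fluence
}

#' Sweep the illumination incident angle
#'
#' Re-solves the steady diffusion problem for each incident angle at a
#' fixed arm interval and tabulates the midline depth profiles.
#'
#' @param angles Incident angles in degrees, each in `[0, 90)`.
#' @param fixed_interval Arm interval (mm), default 14.
#' @param medium,pulse,grid Passed to [solve_fluence()].
#' @param geom Base [illumination_geometry()]; its angle and interval are
#'   overridden per sweep point.
#' @param depths Depths to tabulate (mm).
#' @param ... Further arguments to [solve_fluence()].
#' @return A tibble with columns `angle_deg`, `depth_mm`, `fluence`.
#' @export
sweep_incident_angle <- function(angles, fixed_interval = 14,
                                 medium = lipofundin_1pct(),
                                 pulse = pulse_profile(),
                                 geom = illumination_geometry(),
                                 grid = cartesian_grid(),
                                 depths = seq(0.5, 20, by = 0.5), ...) {
  if (any(angles < 0 | angles >= 90)) {
    stop("angles must lie in [0, 90)", call. = FALSE)
  }
  purrr::map_dfr(angles, function(a) {
    g <- geom
    g$incident_angle_deg <- a
    g$arm_interval <- fixed_interval
    fld <- solve_fluence(medium, pulse, g, grid, mode = "steady", ...)
    dplyr::mutate(fluence_depth_profile(fld, depths = depths),
                  angle_deg = a, .before = 1)
  })
}

#' Sweep the arm interval
#'
#' As [sweep_incident_angle()] but varying the distance between the two
#' fiber arms at a fixed incident angle (default 35 degrees).
#'
#' @param intervals Arm intervals (mm), all > 0.
#' @param fixed_angle Incident angle in degrees, default 35.
#' @inheritParams sweep_incident_angle
#' @return A tibble with columns `interval_mm`, `depth_mm`, `fluence`.
#' @export
sweep_arm_interval <- function(intervals, fixed_angle = 35,
                               medium = lipofundin_1pct(),
                               pulse = pulse_profile(),
                               geom = illumination_geometry(),
                               grid = cartesian_grid(),
                               depths = seq(0.5, 20, by = 0.5), ...) {
  if (any(intervals <= 0)) stop("intervals must be > 0", call. = FALSE)
  purrr::map_dfr(intervals, function(iv) {
    g <- geom
    g$incident_angle_deg <- fixed_angle
    g$arm_interval <- iv
    fld <- solve_fluence(medium, pulse, g, grid, mode = "steady", ...)
    dplyr::mutate(fluence_depth_profile(fld, depths = depths),
                  interval_mm = iv, .before = 1)
  })
}
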