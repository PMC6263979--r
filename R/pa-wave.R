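#' Acoustic wave radiated by the accelerating target surface
#'
#' Integrates the lossless wave equation
#' `(1/(rho c_s^2)) d2p/dt2 - div(grad p / rho) = 0` in the medium
#' outside the target (the pressure inside the target is not modelled;
#' only the surface's normal acceleration enters).  Spherical symmetry is
#' exploited through the substitution `q = r p`, which obeys the plane
#' wave equation exactly, integrated by leapfrog finite differences.  The
#' boundary-acceleration drive enters at the target surface
#' (`dp/dr = -rho u''`) and the outer boundary applies the outgoing
#' characteristic `p_t + c_s p_r + c_s p / r = 0`, which is exact for a
#' spherical wave in the `q` variable.
#'
#' @param scene A [spherical_target_scene()].
#' @param surface_drive Tibble from [boundary_acceleration_source()]
#'   (`time_ns`, `u_ddot`).
#' @param dr Radial step (micrometers, default 0.1).
#' @param cfl Courant number `c_s dt / dr`, must be `<= 0.5`.
#' @param t_end End time (ns); default covers the drive plus the transit
#'   time to the outer radius.
#' @param snapshot_every Store a full radial snapshot every this many
#'   steps (default 50).
#' @return A `pressure_field`: list with the observation trace
#'   (`time_ns`, `p_obs`, Pa), observation radius, snapshot matrix
#'   (radius x snapshot) with `snapshot_times_ns`, and grid metadata.
#' @export
solve_acoustic_wave <- function(scene, surface_drive, dr = 0.1, cfl = 0.5,
                                t_end = NULL, snapshot_every = 50L) {
  stopifnot(inherits(scene, "spherical_target_scene"))
  if (cfl > 0.5) stop("CFL number must be <= 0.5", call. = FALSE)
  cs <- scene$medium_material$sound_speed        # m/s
  rho <- scene$medium_material$density
  cs_umns <- cs * 1e-3                           # um per ns
  dt <- cfl * dr / cs_umns                       # ns
  r0 <- scene$target_radius
  rmax <- scene$medium_radius
  if (is.null(t_end)) {
    t_end <- max(surface_drive$time_ns) + (rmax - r0) / cs_umns
  }
  r <- seq(r0, rmax, by = dr)                    # um
  n <- length(r)
  nt <- ceiling(t_end / dt) + 1L
  times <- (seq_len(nt) - 1) * dt
  udd <- stats::approx(surface_drive$time_ns, surface_drive$u_ddot,
                       xout = times, rule = 2)$y

  # q = r p, SI amplitudes with r in meters
  rm <- r * 1e-6
  q_prev <- numeric(n); q_cur <- numeric(n)
  c2 <- cfl^2
  i_obs <- which.min(abs(r - (r0 + scene$observation_offset)))
  p_obs <- numeric(nt)
  snaps <- NULL; snap_t <- NULL
  drm <- dr * 1e-6
  store <- seq(snapshot_every, nt, by = snapshot_every)
  snaps <- matrix(0, n, length(store)); snap_t <- times[store]; si <- 1L
  for (m in 2:nt) {
    q_next <- numeric(n)
    q_next[2:(n - 1)] <- 2 * q_cur[2:(n - 1)] - q_prev[2:(n - 1)] +
      c2 * (q_cur[3:n] - 2 * q_cur[2:(n - 1)] + q_cur[1:(n - 2)])
    # surface drive via ghost node: q_r(r0) = q/r0 - rho r0 u''
    qr0 <- q_cur[1] / rm[1] - rho * rm[1] * udd[m - 1]
    ghost <- q_cur[2] - 2 * drm * qr0
    q_next[1] <- 2 * q_cur[1] - q_prev[1] +
      c2 * (q_cur[2] - 2 * q_cur[1] + ghost)
    # outgoing characteristic at the outer edge (exact in q)
    q_next[n] <- q_cur[n] - cfl * (q_cur[n] - q_cur[n - 1])
    q_prev <- q_cur; q_cur <- q_next
    p_obs[m] <- q_cur[i_obs] / rm[i_obs]
    if (si <= length(store) && m == store[si]) {
      snaps[, si] <- q_cur / rm; si <- si + 1L
    }
  }
  structure(list(time_ns = times, p_obs = p_obs, r_obs_um = r[i_obs],
                 r_um = r, snapshots = snaps, snapshot_times_ns = snap_t,
                 scene = scene),
            class = "pressure_field")
}

#' @export
print.pressure_field <- function(x, ...) {
  cat(sprintf("<pressure_field> obs at %.2f um: peak |p| = %.4g Pa over %.0f ns\n",
              x$r_obs_um, max(abs(x$p_obs)), max(x$time_ns)))
  invisible(x)
}

#' 2-D X-Z slice acoustic wavefield
#'
#' Renders the outward-propagating wavefield on an X-Z plane through the
#' target center: a monopole source trace (the surface acceleration
#' drive) injected at the target location on a uniform grid, leapfrog
#' integration, first-order absorbing edges.  Intended for qualitative
#' time-sequence snapshots of the spherical wave leaving the target; the
#' radial solver is the quantitative path.
#'
#' @param scene A [spherical_target_scene()].
#' @param surface_drive Tibble from [boundary_acceleration_source()].
#' @param extent Half-width of the slice (micrometers, default 300).
#' @param h Grid step (micrometers, default 2).
#' @param snapshot_times_ns Times (ns) at which to store snapshots.
#' @param cfl Courant number (<= 0.7 for 2-D stability; default 0.5).
#' @return List with `snapshots` (list of matrices), `x_um`, `z_um`,
#'   `snapshot_times_ns`.
#' @export
solve_acoustic_wave_2d <- function(scene, surface_drive, extent = 300,
                                   h = 2, snapshot_times_ns = c(50, 100, 150, 200),
                                   cfl = 0.5) {
  cs <- scene$medium_material$sound_speed * 1e-3   # um/ns
  dt <- cfl * h / cs / sqrt(2)
  nt <- ceiling(max(snapshot_times_ns) / dt) + 1L
  times <- (seq_len(nt) - 1) * dt
  udd <- stats::approx(surface_drive$time_ns, surface_drive$u_ddot,
                       xout = times, rule = 2)$y
  x <- seq(-extent, extent, by = h)
  n <- length(x)
  ic <- which.min(abs(x))
  lam2 <- (cs * dt / h)^2
  p_prev <- matrix(0, n, n); p_cur <- matrix(0, n, n)
  snaps <- vector("list", length(snapshot_times_ns))
  snap_idx <- vapply(snapshot_times_ns, function(t) which.min(abs(times - t)),
                     integer(1))
  cou <- cs * dt / h
  for (m in 2:nt) {
    lap <- matrix(0, n, n)
    lap[2:(n - 1), 2:(n - 1)] <-
      p_cur[1:(n - 2), 2:(n - 1)] + p_cur[3:n, 2:(n - 1)] +
      p_cur[2:(n - 1), 1:(n - 2)] + p_cur[2:(n - 1), 3:n] -
      4 * p_cur[2:(n - 1), 2:(n - 1)]
    p_next <- 2 * p_cur - p_prev + lam2 * lap
    p_next[ic, ic] <- p_next[ic, ic] + dt^2 * udd[m - 1] * 1e-6
    # first-order absorbing edges
    p_next[1, ] <- p_cur[2, ] + (cou - 1) / (cou + 1) * (p_next[2, ] - p_cur[1, ])
    p_next[n, ] <- p_cur[n - 1, ] + (cou - 1) / (cou + 1) * (p_next[n - 1, ] - p_cur[n, ])
    p_next[, 1] <- p_cur[, 2] + (cou - 1) / (cou + 1) * (p_next[, 2] - p_cur[, 1])
    p_next[, n] <- p_cur[, n - 1] + (cou - 1) / (cou + 1) * (p_next[, n - 1] - p_cur[, n])
    p_prev <- p_cur; p_cur <- p_next
    hit <- which(snap_idx == m)
    for (s in hit) snaps[[s]] <- p_cur
  }
  list(snapshots = snaps, x_um = x, z_um = x,
       snapshot_times_ns = times[snap_idx])
}
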