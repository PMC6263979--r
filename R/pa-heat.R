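#' Transient heat conduction around the spherical target
#'
#' Integrates `rho C dT/dt = div(k grad T) + Q` in spherical symmetry over
#' target plus medium, with continuity of temperature and flux at the
#' interface (finite-volume fluxes with harmonic-mean face conductivity)
#' and `T = T_ref` at the outer boundary.  The heat source acts uniformly
#' inside the target (the sphere is optically thin compared with the
#' illumination scale).  Time stepping is implicit Euler with a sparse
#' factorization reused across steps, so it is unconditionally stable.
#'
#' @param scene A [spherical_target_scene()].
#' @param pulse A [pulse_profile()] (sets the default time resolution,
#'   `dt = tau_p / 20`, and span).
#' @param Q_drive Either a function of time (ns) returning the volumetric
#'   heat rate inside the target (W/m^3), or a single fluence-rate
#'   amplitude (W/cm^2) that is modulated by the Gaussian pulse envelope
#'   and converted via [heat_source_density()].
#' @param dr Radial step (micrometers, default 0.1).
#' @param dt Time step (ns); must satisfy `dt <= tau_p / 10`.
#' @param t_end End time (ns, default `tau_center + 14 * tau_p`).
#' @return A `heat_solution`: list with `time_ns`, `r_um`, temperature
#'   matrix `T` (radius x time, K), the volume-averaged target temperature
#'   trace `T_target`, and the scene.
#' @export
solve_heat <- function(scene, pulse = pulse_profile(), Q_drive,
                       dr = 0.1, dt = NULL, t_end = NULL) {
  stopifnot(inherits(scene, "spherical_target_scene"))
  if (is.null(dt)) dt <- pulse$tau_p / 20
  if (dt > pulse$tau_p / 10 + 1e-12) {
    stop("`dt` must resolve the pulse: dt <= tau_p / 10", call. = FALSE)
  }
  if (is.null(t_end)) t_end <- pulse$tau_center + 14 * pulse$tau_p
  times <- seq(0, t_end, by = dt)

  if (is.function(Q_drive)) {
    Qt <- Q_drive(times)
  } else {
    shape <- exp(-4 * (times - pulse$tau_center)^2 / pulse$tau_p^2)
    Qt <- heat_source_density(Q_drive, scene$target_material) * shape
  }

  # node-centered radial grid in SI units
  r <- seq(0, scene$medium_radius, by = dr) * 1e-6   # m
  n <- length(r)
  drm <- dr * 1e-6
  in_target <- r <= scene$target_radius * 1e-6 + 1e-12
  k_node <- ifelse(in_target, scene$target_material$thermal_conductivity,
                   scene$medium_material$thermal_conductivity)
  rhoC <- ifelse(in_target,
                 scene$target_material$density * scene$target_material$heat_capacity,
                 scene$medium_material$density * scene$medium_material$heat_capacity)
  r_face <- (r[-1] + r[-n]) / 2
  k_face <- 2 * k_node[-1] * k_node[-n] / (k_node[-1] + k_node[-n])
  A_face <- 4 * pi * r_face^2
  r_out <- c(r_face, r[n] + drm / 2)
  r_in <- c(0, r_face)
  V <- (4 / 3) * pi * (r_out^3 - r_in^3)
  cond <- A_face * k_face / drm                       # W/K per interior face

  # tridiagonal implicit Euler operator: (rhoC V / dt + L) T' = rhoC V/dt T + Q V
  diag0 <- rhoC * V / (dt * 1e-9)
  lower <- -cond
  upper <- -cond
  dmain <- diag0
  dmain[-n] <- dmain[-n] + cond
  dmain[-1] <- dmain[-1] + cond
  # outer Dirichlet: pin the last node (zero its coupling to n-1 only;
  # row n-1 keeps its flux link to the boundary value)
  dmain[n] <- 1; lower[n - 1] <- 0
  up <- upper
  M <- Matrix::sparseMatrix(
    i = c(seq_len(n), 2:n, seq_len(n - 1)),
    j = c(seq_len(n), 1:(n - 1), 2:n),
    x = c(dmain, lower, up), dims = c(n, n))
  fac <- Matrix::lu(M)

  Tm <- matrix(scene$T_ref, n, length(times))
  Tt <- numeric(length(times)); Tt[1] <- scene$T_ref
  Vt <- V[in_target]
  phi_prev <- rep(scene$T_ref, n)
  for (m in seq_along(times)[-1]) {
    b <- diag0 * phi_prev
    b[in_target] <- b[in_target] + Qt[m] * V[in_target]
    b[n] <- scene$T_ref
    phi_prev <- as.numeric(Matrix::solve(fac, b))
    Tm[, m] <- phi_prev
    Tt[m] <- sum(phi_prev[in_target] * Vt) / sum(Vt)
  }
  structure(list(time_ns = times, r_um = r * 1e6, T = Tm, T_target = Tt,
                 Q_trace = Qt, scene = scene),
            class = "heat_solution")
}

#' Thermal strain
#'
#' Linear thermal strain `beta (T - T_ref)`, positive on heating
#' (expansion).  Vectorized over `T`.
#'
#' @param T Temperature (K).
#' @param T_ref Reference temperature (K).
#' @param beta Linear thermal expansion coefficient (1/K).
#' @return Strain (dimensionless).
#' @export
thermal_strain <- function(T, T_ref, beta) {
  beta * (T - T_ref)
}

#' Surface displacement and boundary acceleration of the heated target
#'
#' Quasi-static strain-to-displacement map: the radial surface
#' displacement is `u(t) = R_target * strain(t)` with the strain from the
#' volume-averaged target temperature; the acceleration `u''(t)` is
#' obtained by central second differences on a lightly Gaussian-smoothed
#' `u(t)` (smoothing width one time step) to control differentiation
#' noise.  `u''` drives the acoustic boundary condition
#' `n . (grad p / rho) = -u''` at the target surface.
#'
#' @param scene A [spherical_target_scene()].
#' @param heat A `heat_solution` from [solve_heat()].
#' @return A tibble with columns `time_ns`, `u_m` (surface displacement,
#'   m) and `u_ddot` (surface acceleration, m/s^2).
#' @export
boundary_acceleration_source <- function(scene, heat) {
  stopifnot(inherits(heat, "heat_solution"))
  beta <- scene$target_material$thermal_expansion
  eps <- thermal_strain(heat$T_target, scene$T_ref, beta)
  u <- scene$target_radius * 1e-6 * eps                   # m
  dt_s <- diff(heat$time_ns[1:2]) * 1e-9
  # Gaussian smoothing, sigma = one step
  kw <- 4
  kern <- exp(-0.5 * ((-kw):kw)^2)
  kern <- kern / sum(kern)
  upad <- c(rep(u[1], kw), u, rep(u[length(u)], kw))
  us <- stats::filter(upad, kern, sides = 2)[(kw + 1):(kw + length(u))]
  n <- length(us)
  udd <- c(0, diff(us, differences = 2) / dt_s^2, 0)
  tibble::tibble(time_ns = heat$time_ns, u_m = as.numeric(us), u_ddot = udd)
}
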