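#' Homogeneous optical medium
#'
#' Describes a homogeneous scattering medium by its absorption coefficient,
#' scattering coefficient, scattering anisotropy and refractive index.  The
#' bundled [lipofundin_1pct()] preset plays the role of the 1% Lipofundin
#' tissue mimic commonly used in photoacoustic bench work.
#'
#' @param mu_a Absorption coefficient (1/cm), non-negative.
#' @param mu_s Scattering coefficient (1/cm), non-negative.  If `g = 0` this
#'   equals the reduced scattering coefficient.
#' @param g Scattering anisotropy (mean cosine of the scattering angle),
#'   in `[-1, 1]`.
#' @param n Refractive index, `>= 1`.
#' @param name Optional label.
#' @return An object of class `optical_medium`.
#' @examples
#' m <- optical_medium(mu_a = 0.026, mu_s = 6.31, g = 0, n = 1.35)
#' transport_mean_free_path(m)
#' @export
optical_medium <- function(mu_a, mu_s, g = 0, n = 1.33, name = "medium") {
  stopifnot(is.numeric(mu_a), is.numeric(mu_s), is.numeric(g), is.numeric(n))
  if (mu_a < 0) stop("`mu_a` must be >= 0", call. = FALSE)
  if (mu_s < 0) stop("`mu_s` must be >= 0", call. = FALSE)
  if (abs(g) > 1) stop("`g` must lie in [-1, 1]", call. = FALSE)
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  structure(
    list(mu_a = mu_a, mu_s = mu_s, g = g, n = n, name = name),
    class = "optical_medium"
  )
}

#' @export
print.optical_medium <- function(x, ...) {
  cat(sprintf(
    "<optical_medium '%s'>  mu_a = %g /cm, mu_s' = %g /cm, g = %g, n = %g\n",
    x$name, x$mu_a, reduced_scattering(x$mu_s, x$g), x$g, x$n
  ))
  invisible(x)
}

#' 1% Lipofundin tissue-mimicking medium
#'
#' Optical properties of a 1% Lipofundin emulsion near 785 nm
#' (`mu_a = 0.026` 1/cm, reduced scattering `6.31` 1/cm, `n = 1.35`),
#' the standard bench-top stand-in for soft tissue.  The scattering
#' coefficient is stored as already-reduced (`g = 0`).
#'
#' @return An `optical_medium`.
#' @export
lipofundin_1pct <- function() {
  optical_medium(mu_a = 0.026, mu_s = 6.31, g = 0, n = 1.35,
                 name = "1% Lipofundin")
}

#' Reduced scattering coefficient
#'
#' `mu_s' = (1 - g) * mu_s`: the scattering coefficient corrected for
#' forward-peaked anisotropy.
#'
#' @param mu_s Scattering coefficient (1/cm).
#' @param g Anisotropy factor in `[-1, 1]`.
#' @return Reduced scattering coefficient (1/cm).
#' @export
reduced_scattering <- function(mu_s, g) {
  if (any(mu_s < 0)) stop("`mu_s` must be >= 0", call. = FALSE)
  if (any(abs(g) > 1)) stop("`g` must lie in [-1, 1]", call. = FALSE)
  (1 - g) * mu_s
}

#' Transport mean free path
#'
#' The distance over which photon directions randomize,
#' `Z0 = 1 / (mu_a + mu_s')`.  In diffusion models of collimated
#' illumination the source is buried at this depth below the surface.
#'
#' @param medium An [optical_medium()].
#' @return Length in cm.
#' @export
transport_mean_free_path <- function(medium) {
  stopifnot(inherits(medium, "optical_medium"))
  musp <- reduced_scattering(medium$mu_s, medium$g)
  denom <- medium$mu_a + musp
  if (denom <= 0) stop("mu_a + mu_s' must be > 0", call. = FALSE)
  1 / denom
}

#' Diffusion coefficient of a medium
#'
#' `D = 1 / (3 (mu_a + mu_s'))`, in cm.
#' @param medium An [optical_medium()].
#' @return Diffusion coefficient (cm).
#' @export
diffusion_coefficient <- function(medium) {
  transport_mean_free_path(medium) / 3
}

#' Effective internal reflection coefficient
#'
#' Empirical curve fit (Egan and Hilgeman) for the internal reflection of
#' uniformly diffuse radiation at a refractive-index-mismatched boundary:
#' `R_eff = -1.4399 n^-2 + 0.7099 n^-1 + 0.6681 + 0.0636 n`.
#'
#' @param n Refractive index of the medium (> 0).
#' @return Dimensionless reflection coefficient.
#' @export
effective_internal_reflection <- function(n) {
  if (any(n <= 0)) stop("`n` must be > 0", call. = FALSE)
  -1.4399 / n^2 + 0.7099 / n + 0.6681 + 0.0636 * n
}

#' Robin boundary coefficient
#'
#' Proportionality constant `h` in the mixed boundary condition
#' `-D grad(phi) . n = h phi` applied at the medium surface:
#' `h = 0.5 (1 - R_eff) / (1 + R_eff)` with `R_eff` from
#' [effective_internal_reflection()].  As `R_eff -> 1` (perfect internal
#' reflection) the coefficient tends to zero and the wall becomes
#' non-draining.
#'
#' @inheritParams effective_internal_reflection
#' @return Dimensionless boundary coefficient.
#' @export
robin_boundary_coefficient <- function(n) {
  reff <- effective_internal_reflection(n)
  0.5 * (1 - reff) / (1 + reff)
}

#' Laser pulse profile
#'
#' Temporally Gaussian pulse description: per-pulse energy `Wp` (mJ),
#' width `tau_p` (ns) and peak time `tau_center` (ns).
#'
#' @param Wp Pulse energy in mJ (> 0).  Default 20 mJ.
#' @param tau_p Pulse width in ns (> 0).  Default 5 ns.
#' @param tau_center Pulse peak time in ns (>= 0).  Default 30 ns.
#' @return A `pulse_profile` object.
#' @export
pulse_profile <- function(Wp = 20, tau_p = 5, tau_center = 30) {
  if (Wp <= 0) stop("`Wp` must be > 0", call. = FALSE)
  if (tau_p <= 0) stop("`tau_p` must be > 0", call. = FALSE)
  if (tau_center < 0) stop("`tau_center` must be >= 0", call. = FALSE)
  structure(list(Wp = Wp, tau_p = tau_p, tau_center = tau_center),
            class = "pulse_profile")
}

#' Temporal source density of a Gaussian pulse
#'
#' Evaluates the volumetric source term
#' `P0(t) = mu_s' Wp (2 / (pi sqrt(pi) tau_p)) exp(-4 (t - tau_center)^2 / tau_p^2)`.
#' The time integral of the Gaussian factor together with the prefactor is
#' `mu_s' Wp / pi`; this scale constant is fixed by the printed prefactor
#' and carried through consistently (relative fluence results are
#' insensitive to it).
#'
#' @param t Time (ns), vectorized.
#' @param medium An [optical_medium()] supplying `mu_s'`.
#' @param pulse A [pulse_profile()].
#' @return Source density values, same length as `t`.
#' @export
gaussian_pulse_power <- function(t, medium, pulse) {
  stopifnot(inherits(medium, "optical_medium"), inherits(pulse, "pulse_profile"))
  musp <- reduced_scattering(medium$mu_s, medium$g)
  pref <- 2 / (pi * sqrt(pi) * pulse$tau_p)
  musp * pulse$Wp * pref * exp(-4 * (t - pulse$tau_center)^2 / pulse$tau_p^2)
}

#' Footprint of the diverging beam after the ballistic segment
#'
#' After propagating the transport mean free path `z0` into the medium, a
#' beam launched from a fiber bundle of numerical aperture `NA` has grown
#' by `delta = z0 * tan(asin(NA / n))` in each dimension (one total
#' increment per dimension; this convention reproduces the printed
#' footprints for standard fiber-bundle arms).
#'
#' @param beam_width Long-axis output dimension (mm).
#' @param beam_height Short-axis output dimension (mm).
#' @param na Fiber numerical aperture (dimensionless, `< n`).
#' @param n Medium refractive index.
#' @param z0 Ballistic path length (mm).
#' @return Named numeric vector `c(width, height)` in mm.
#' @examples
#' diverged_source_footprint(16.5, 0.8, 0.22, 1.35, 1.578)
#' @export
diverged_source_footprint <- function(beam_width, beam_height, na, n, z0) {
  if (beam_width <= 0 || beam_height <= 0) {
    stop("beam dimensions must be > 0", call. = FALSE)
  }
  if (na < 0 || z0 < 0 || n <= 0) stop("invalid parameters", call. = FALSE)
  if (na >= n) stop("`na` must be smaller than `n`", call. = FALSE)
  delta <- z0 * tan(asin(na / n))
  c(width = beam_width + delta, height = beam_height + delta)
}
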