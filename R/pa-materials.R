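#' Thermo-mechanical material properties
#'
#' Properties entering the coupled heating / thermal-expansion / acoustic
#' chain.  Young's modulus and Poisson ratio are carried for forward
#' compatibility with a full solid-mechanics modal treatment; the default
#' quasi-static strain-to-displacement path does not use them.
#'
#' @param heat_capacity Specific heat capacity C (J/(kg K)).
#' @param thermal_conductivity k (W/(m K)).
#' @param density rho (kg/m^3).
#' @param thermal_expansion Linear thermal expansion coefficient beta (1/K).
#' @param youngs_modulus E (Pa).
#' @param poisson_ratio nu, in (-1, 0.5).
#' @param heat_yield Y, fraction of absorbed fluence converted to heat,
#'   in (0, 1].
#' @param sound_speed c_s (m/s).
#' @param mu_a Optical absorption coefficient (1/cm).
#' @param name Label.
#' @return A `thermo_material` object.
#' @export
thermo_material <- function(heat_capacity, thermal_conductivity, density,
                            thermal_expansion, youngs_modulus = 1e9,
                            poisson_ratio = 0.3, heat_yield = 1,
                            sound_speed = 1500, mu_a = 0.026,
                            name = "material") {
  vals <- c(heat_capacity, thermal_conductivity, density,
            thermal_expansion, youngs_modulus, sound_speed)
  if (any(vals <= 0)) stop("physical fields must be > 0", call. = FALSE)
  if (poisson_ratio <= -1 || poisson_ratio >= 0.5) {
    stop("`poisson_ratio` must lie in (-1, 0.5)", call. = FALSE)
  }
  if (heat_yield <= 0 || heat_yield > 1) {
    stop("`heat_yield` must lie in (0, 1]", call. = FALSE)
  }
  if (mu_a < 0) stop("`mu_a` must be >= 0", call. = FALSE)
  structure(list(heat_capacity = heat_capacity,
                 thermal_conductivity = thermal_conductivity,
                 density = density, thermal_expansion = thermal_expansion,
                 youngs_modulus = youngs_modulus,
                 poisson_ratio = poisson_ratio, heat_yield = heat_yield,
                 sound_speed = sound_speed, mu_a = mu_a, name = name),
            class = "thermo_material")
}

#' Default graphite target material
#'
#' Textbook bulk constants for polycrystalline graphite.  Absolute PA
#' amplitudes depend on these constants, so all shipped design checks are
#' ratio-based and cancel them.
#' @return A `thermo_material`.
#' @export
graphite_material <- function() {
  thermo_material(heat_capacity = 710, thermal_conductivity = 120,
                  density = 2200, thermal_expansion = 8e-6,
                  youngs_modulus = 10e9, poisson_ratio = 0.2,
                  heat_yield = 1, sound_speed = 3000, mu_a = 500,
                  name = "graphite")
}

#' Default aqueous (1% Lipofundin) surrounding material
#'
#' Water-like thermal/acoustic constants for the dilute lipid emulsion.
#' @return A `thermo_material`.
#' @export
lipofundin_material <- function() {
  thermo_material(heat_capacity = 4180, thermal_conductivity = 0.6,
                  density = 1000, thermal_expansion = 7e-5,
                  youngs_modulus = 2.2e9, poisson_ratio = 0.49,
                  heat_yield = 1, sound_speed = 1500, mu_a = 0.026,
                  name = "1% Lipofundin")
}

#' Micro-scale spherical target scene
#'
#' A strongly absorbing micro-sphere (graphite role) embedded in a
#' water-like medium sphere, with an observation point just outside the
#' target surface: the canonical micro-scale PA generation geometry.
#'
#' @param target_radius Target radius in micrometers (default 6).
#' @param medium_radius Medium radius in micrometers (default 300).
#' @param target_material,medium_material [thermo_material()] objects.
#' @param observation_offset Distance of the observation point from the
#'   target surface (micrometers, default 1).
#' @param T_ref Reference temperature (K).
#' @return A `spherical_target_scene`.
#' @export
spherical_target_scene <- function(target_radius = 6, medium_radius = 300,
                                   target_material = graphite_material(),
                                   medium_material = lipofundin_material(),
                                   observation_offset = 1,
                                   T_ref = 293.15) {
  if (target_radius >= medium_radius) {
    stop("`target_radius` must be smaller than `medium_radius`", call. = FALSE)
  }
  if (observation_offset < 0) {
    stop("`observation_offset` must be >= 0", call. = FALSE)
  }
  structure(list(target_radius = target_radius, medium_radius = medium_radius,
                 target_material = target_material,
                 medium_material = medium_material,
                 observation_offset = observation_offset, T_ref = T_ref),
            class = "spherical_target_scene")
}

#' Volumetric heat source density from absorbed fluence
#'
#' `Q = phi mu_a Y`: local fluence rate (W/cm^2) times the absorption
#' coefficient (1/cm) times the heat yield, converted to W/m^3.
#'
#' @param fluence_rate Fluence rate at the target (W/cm^2), vectorized.
#' @param material A [thermo_material()] supplying `mu_a` and `heat_yield`.
#' @return Heat rate density in W/m^3.
#' @export
heat_source_density <- function(fluence_rate, material) {
  stopifnot(inherits(material, "thermo_material"))
  if (any(fluence_rate < 0)) stop("fluence must be >= 0", call. = FALSE)
  fluence_rate * material$mu_a * material$heat_yield * 1e6  # W/cm^3 -> W/m^3
}
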