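test_that("heat source density is linear in fluence, absorption and yield", {
  gm <- graphite_material()
  expect_equal(heat_source_density(0, gm), 0)
  q1 <- heat_source_density(100, gm)
  gm2 <- gm; gm2$mu_a <- 2 * gm$mu_a
  expect_equal(heat_source_density(100, gm2), 2 * q1)
  expect_equal(heat_source_density(200, gm), 2 * q1)
  expect_equal(q1, 100 * gm$mu_a * 1e6)
  expect_error(heat_source_density(-1, gm), "fluence")
})

test_that("unheated scene stays at the reference temperature", {
  sc <- spherical_target_scene(medium_radius = 50)
  h <- solve_heat(sc, pulse_profile(), Q_drive = 0, dr = 0.5, t_end = 50)
  expect_true(all(abs(h$T - sc$T_ref) < 1e-9))
})

test_that("near-adiabatic heating matches the enthalpy quadrature oracle", {
  gm <- graphite_material()
  # conduction suppressed: tiny conductivities isolate the storage term
  gm$thermal_conductivity <- 1e-9
  mm <- lipofundin_material(); mm$thermal_conductivity <- 1e-9
  sc <- spherical_target_scene(target_radius = 6, medium_radius = 30,
                               target_material = gm, medium_material = mm)
  pul <- pulse_profile()
  phi_peak <- 1e5
  h <- solve_heat(sc, pul, Q_drive = phi_peak, dr = 0.1, t_end = 70)
  # oracle: dT = integral(Q dt) / (rho C)
  q_int <- stats::integrate(function(t) {
    heat_source_density(phi_peak, gm) *
      exp(-4 * (t - pul$tau_center)^2 / pul$tau_p^2)
  }, 0, 70)$value * 1e-9                       # W/m^3 * s
  want <- q_int / (gm$density * gm$heat_capacity)
  got <- h$T_target[length(h$T_target)] - sc$T_ref
  expect_equal(got / want, 1, tolerance = 0.01)
})

test_that("target temperature peaks at or after the pulse peak", {
  sc <- spherical_target_scene(medium_radius = 60)
  h <- solve_heat(sc, pulse_profile(), Q_drive = 1e5, dr = 0.2, t_end = 80)
  expect_gte(h$time_ns[which.max(h$T_target)], 30)
})

test_that("thermal strain is linear and vanishes at the reference", {
  expect_equal(thermal_strain(300, 300, 8e-6), 0)
  expect_equal(thermal_strain(310, 300, 0), 0)
  expect_equal(thermal_strain(320, 300, 8e-6),
               2 * thermal_strain(310, 300, 8e-6))
})

test_that("surface drive is linear in pulse energy and bipolar in acceleration", {
  sc <- spherical_target_scene(medium_radius = 60)
  h1 <- solve_heat(sc, pulse_profile(), Q_drive = 1e5, dr = 0.2, t_end = 80)
  h2 <- solve_heat(sc, pulse_profile(), Q_drive = 2e5, dr = 0.2, t_end = 80)
  d1 <- boundary_acceleration_source(sc, h1)
  d2 <- boundary_acceleration_source(sc, h2)
  expect_lt(max(abs(d2$u_m - 2 * d1$u_m)) / max(abs(d2$u_m)), 1e-6)
  # constant temperature -> acceleration at solver-roundoff level only
  h0 <- solve_heat(sc, pulse_profile(), Q_drive = 0, dr = 0.5, t_end = 40)
  d0 <- boundary_acceleration_source(sc, h0)
  expect_lt(max(abs(d0$u_ddot)), 1e-8 * max(abs(d1$u_ddot)))
  # a Gaussian heating pulse gives a sign-changing acceleration
  expect_gt(max(d1$u_ddot), 0)
  expect_lt(min(d1$u_ddot), 0)
})

test_that("radiated wave decays as 1/r, travels at c_s and respects causality", {
  sc <- spherical_target_scene()
  h <- solve_heat(sc, pulse_profile(), Q_drive = 1e5)
  d <- boundary_acceleration_source(sc, h)
  w <- solve_acoustic_wave(sc, d)
  pk <- function(robs) {
    i <- which.min(abs(w$r_um - robs))
    max(abs(w$snapshots[i, ]))
  }
  expect_equal(pk(100) / pk(50), 0.5, tolerance = 0.05)
  expect_equal(pk(200) / pk(100), 0.5, tolerance = 0.05)
  # wavefront speed from snapshot front positions
  front <- function(j) {
    s <- abs(w$snapshots[, j])
    max(w$r_um[s > 0.01 * max(s)])
  }
  cs <- sc$medium_material$sound_speed * 1e-3
  dtj <- w$snapshot_times_ns[100] - w$snapshot_times_ns[50]
  expect_equal((front(100) - front(50)) / dtj, cs, tolerance = 0.05)
  # zero drive -> zero field
  d0 <- d; d0$u_ddot <- 0 * d0$u_ddot
  w0 <- solve_acoustic_wave(sc, d0, t_end = 50)
  expect_true(all(w0$p_obs == 0))
  expect_error(solve_acoustic_wave(sc, d, cfl = 0.9), "CFL")
})

test_that("the chain is linear and does not radiate more than was deposited", {
  sc <- spherical_target_scene()
  w1 <- pa_chain(1e5, sc)
  w2 <- pa_chain(2e5, sc)
  expect_equal(max(abs(w2$p_obs)) / max(abs(w1$p_obs)), 2, tolerance = 0.01)
  # energy sanity at a mid-field radius
  heat <- attr(w1, "heat")
  dt_q <- diff(heat$time_ns[1:2]) * 1e-9
  v_target <- (4 / 3) * pi * (sc$target_radius * 1e-6)^3
  deposited <- sum(heat$Q_trace) * dt_q * v_target         # J
  i <- which.min(abs(w1$r_um - 150))
  rho_c <- sc$medium_material$density * sc$medium_material$sound_speed
  dt_s <- diff(w1$snapshot_times_ns[1:2]) * 1e-9
  radiated <- sum(w1$snapshots[i, ]^2) / rho_c *
    4 * pi * (150e-6)^2 * dt_s
  expect_lt(radiated, deposited)
})

test_that("equal intervals give unit amplitude ratio tracking the fluence ratio", {
  grid <- cartesian_grid(c(80, 60, 30), 1)
  r <- interval_amplitude_ratio(14, 14, grid = grid)
  expect_equal(r$pressure_ratio, 1, tolerance = 1e-6)
  expect_equal(r$fluence_ratio, 1, tolerance = 1e-12)
  r2 <- interval_amplitude_ratio(10, 20, grid = grid)
  expect_gt(r2$pressure_ratio, 1)
  expect_equal(r2$pressure_ratio / r2$fluence_ratio, 1, tolerance = 0.01)
})
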