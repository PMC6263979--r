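test_that("dual-arm source patches conserve energy and mirror symmetry", {
  med <- lipofundin_1pct()
  grid <- small_grid(1)
  geom <- small_geom(incident_angle_deg = 0)
  src <- build_dual_arm_sources(geom, med, grid, unit_scale = 3)
  h <- grid$spacing
  expect_equal(sum(src$values) * h^3, 2 * 3 * (1 - 0.05), tolerance = 1e-10)
  # two patches mirror-symmetric about y = 0 at angle 0
  expect_equal(src$values, src$values[, rev(seq_len(grid$dim[2])), ],
               tolerance = 1e-12)
  expect_equal(src$interval_at_z0, geom$arm_interval)
  # all light reflected -> zero source
  g0 <- small_geom(surface_reflection = 1 - 1e-12)
  s0 <- build_dual_arm_sources(g0, med, grid)
  expect_lt(sum(s0$values), 1e-10)
  # footprint larger than the grid errors
  expect_error(
    build_dual_arm_sources(illumination_geometry(beam_width = 100),
                           med, grid),
    "exceeds")
})

test_that("steady solve satisfies the discrete energy balance to < 1%", {
  fld <- small_steady_field()
  g <- fld$grid
  med <- lipofundin_1pct()
  h <- g$spacing
  mua_mm <- med$mu_a / 10
  D_mm <- 1 / (3 * (mua_mm + 0.631))
  hb <- robin_boundary_coefficient(med$n)
  alpha <- hb * 2 * D_mm / (hb * h + 2 * D_mm)
  phi <- fld$values / 0.1          # back to mJ/mm^2
  absorbed <- sum(mua_mm * phi) * h^3
  boundary <- 0
  for (ax in 1:3) {
    idx_lo <- slice.index(phi, ax) == 1
    idx_hi <- slice.index(phi, ax) == dim(phi)[ax]
    boundary <- boundary + sum(phi[idx_lo | idx_hi]) * alpha * h^2
  }
  injected <- 2 * (0.631 * 20 / pi) * (1 - 0.05)
  expect_equal((absorbed + boundary) / injected, 1, tolerance = 0.01)
})

test_that("steady solve is linear in pulse energy and positive", {
  med <- lipofundin_1pct()
  grid <- small_grid()
  f1 <- solve_fluence(med, pulse_profile(Wp = 10), small_geom(), grid)
  f2 <- solve_fluence(med, pulse_profile(Wp = 20), small_geom(), grid)
  expect_true(all(f1$values >= 0))
  expect_lt(max(abs(f2$values - 2 * f1$values)) / max(f2$values), 1e-8)
})

test_that("fluence decreases monotonically with absorption", {
  grid <- small_grid()
  phis <- vapply(c(0.026, 0.26, 1.3), function(mua) {
    med <- optical_medium(mua, 6.31, 0, 1.35)
    fluence_at_depth(solve_fluence(med, pulse_profile(), small_geom(), grid),
                     10)
  }, numeric(1))
  expect_true(all(diff(phis) < 0))
})

test_that("steady solver matches the infinite-medium Green's function within 5%", {
  # interior point source far from walls; shape comparison over 2-15 mm
  med <- lipofundin_1pct()
  grid <- cartesian_grid(c(72, 72, 72), 0.5)
  src <- array(0, dim = grid$dim)
  ic <- grid$dim %/% 2
  src[ic[1], ic[2], ic[3]] <- 1 / grid$spacing^3
  mua_mm <- med$mu_a / 10
  D_mm <- 1 / (3 * (mua_mm + 0.631))
  sol <- pasim:::.diffusion_solve_cg(as.numeric(src), grid$dim[1],
                                     grid$dim[2], grid$dim[3], D_mm, mua_mm,
                                     grid$spacing,
                                     robin_boundary_coefficient(med$n),
                                     1e-8, 20000L)
  phi <- array(sol$phi, grid$dim)
  x0 <- grid$x[ic[1]]; y0 <- grid$y[ic[2]]; z0 <- grid$z[ic[3]]
  mueff <- sqrt(3 * mua_mm * (mua_mm + 0.631))
  rs <- seq(2, 15, by = 1)
  # sample along the x axis through the source
  got <- vapply(rs, function(r) {
    i <- which.min(abs(grid$x - (x0 + r)))
    phi[i, ic[2], ic[3]]
  }, numeric(1))
  want <- exp(-mueff * rs) / (4 * pi * D_mm * rs)
  scale <- got[rs == 8] / want[rs == 8]
  expect_lt(max(abs(got / (want * scale) - 1)), 0.05)
})

test_that("angle-0 arms give a y-mirror-symmetric field", {
  fld <- solve_fluence(lipofundin_1pct(), pulse_profile(),
                       small_geom(incident_angle_deg = 0), small_grid())
  v <- fld$values
  expect_equal(v, v[, rev(seq_len(dim(v)[2])), ], tolerance = 1e-6)
})

test_that("midpoint fluence is grid-converged to < 2% under halving", {
  med <- lipofundin_1pct()
  geom <- illumination_geometry()
  g1 <- cartesian_grid(c(80, 60, 40), 1)
  g2 <- cartesian_grid(c(80, 60, 40), 0.5)
  p1 <- fluence_at_depth(solve_fluence(med, pulse_profile(), geom, g1), 10)
  p2 <- fluence_at_depth(solve_fluence(med, pulse_profile(), geom, g2), 10)
  expect_equal(p1 / p2, 1, tolerance = 0.02)
})

test_that("transient integral reproduces the steady field", {
  med <- lipofundin_1pct()
  geom <- small_geom()
  grid <- cartesian_grid(c(20, 20, 16), 2)
  tf <- solve_fluence(med, pulse_profile(), geom, grid, mode = "transient",
                      t_end = 60)
  sf <- solve_fluence(med, pulse_profile(), geom, grid)
  expect_true(all(tf$values >= 0))
  expect_true(all(diff(tf$time_axis) > 0))
  dt_s <- diff(tf$time_axis[1:2]) * 1e-9
  ti <- apply(tf$values, 1:3, sum) * dt_s          # W/cm^2 -> J/cm^2
  i <- which(sf$values == max(sf$values), arr.ind = TRUE)[1, ]
  expect_equal(ti[i[1], i[2], i[3]] / sf$values[i[1], i[2], i[3]], 1,
               tolerance = 0.01)
})

test_that("depth profiles behave on uniform and solved fields", {
  g <- small_grid()
  uni <- fluence_field(g, array(2, dim = g$dim))
  prof <- fluence_depth_profile(uni, depths = seq(1, 20, by = 1))
  expect_true(all(abs(prof$fluence - 2) < 1e-12))
  prof2 <- fluence_depth_profile(small_steady_field(),
                                 depths = seq(0.5, 20, by = 0.5))
  expect_true(all(prof2$fluence >= 0))
  expect_error(fluence_depth_profile(uni, depths = 100), "outside")
})

test_that("sweep tables are deterministic and correctly keyed", {
  grid <- small_grid()
  sw <- sweep_arm_interval(c(8, 12), fixed_angle = 35,
                           geom = small_geom(), grid = grid,
                           depths = c(5, 10))
  sw2 <- sweep_arm_interval(c(8), fixed_angle = 35,
                            geom = small_geom(), grid = grid,
                            depths = c(5, 10))
  # identical configurations reproduce identical columns
  expect_identical(sw$fluence[sw$interval_mm == 8], sw2$fluence)
  expect_true(all(sw$fluence[sw$interval_mm == 12] <
                    sw$fluence[sw$interval_mm == 8]))
  expect_error(sweep_incident_angle(c(-5, 20), grid = grid), "0, 90")
  expect_error(sweep_arm_interval(c(0, 10), grid = grid), "> 0")
})
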