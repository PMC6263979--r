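test_that("the two-hair phantom encodes the edge-gap convention", {
  ph <- make_two_hair_phantom()
  expect_length(ph$primitives, 2)
  centers <- vapply(ph$primitives, function(p) p$center[2], numeric(1))
  expect_equal(diff(sort(centers)) * 1000, 180 + 150)
  expect_equal(unique(vapply(ph$primitives, function(p) p$center[3],
                             numeric(1))), 10.2)
  ph_c <- make_two_hair_phantom(gap_convention = "center")
  centers_c <- vapply(ph_c$primitives, function(p) p$center[2], numeric(1))
  expect_equal(diff(sort(centers_c)) * 1000, 180)
})

test_that("the multi-target phantom has the catalogued primitives in window", {
  ph <- make_multi_target_phantom()
  expect_length(ph$primitives, 4)
  d <- sort(unname(vapply(ph$primitives, function(p) p$diameter_um,
                          numeric(1))))
  expect_equal(d, c(150, 250, 250, 500))
  ras <- rasterize_phantom(ph)
  zs <- ras$scatterers$z
  expect_true(all(zs >= 8.5 & zs <= 11))
  # crosses the 35-mm scan length
  expect_gt(diff(range(ras$scatterers$y)), 30)
})

test_that("occlusion changes are confined to the flagged branch", {
  base <- make_vessel_scene(occluded = FALSE)
  occ <- make_vessel_scene(occluded = TRUE, occlusion_factor = 0.8)
  rb <- rasterize_phantom(base$spec)$mu_a
  ro <- rasterize_phantom(occ$spec)$mu_a
  diff3 <- apply(abs(rb - ro), c(1, 2), max)
  expect_true(any(diff3 > 0))
  expect_true(all(diff3[!occ$change_mask] == 0))
  # factor is configurable
  occ2 <- make_vessel_scene(occluded = TRUE, occlusion_factor = 0.5)
  mu2 <- occ2$spec$primitives$branch_b$mu_a_rel
  expect_equal(mu2, 0.5)
})

test_that("oxygenation scenes round-trip through unmixing", {
  sc <- make_oxygenation_scene(n = 60, seed = 3)
  cm <- unmix_two_wavelength(sc$mu_a_l1, sc$mu_a_l2, 750, 850)
  expect_lt(max(abs(cm$so2 - sc$so2_true)), 1e-9)
  expect_lt(max(abs(cm$hbt - sc$hbt_true)) / max(sc$hbt_true), 1e-9)
  expect_true(all(sc$so2_true[sc$tumor_mask] <= 0.6))
  expect_true(all(sc$so2_true[!sc$tumor_mask] >= 0.9))
  # 5% multiplicative noise keeps the median SO2 error under 0.05
  set.seed(99)
  noisy1 <- sc$mu_a_l1 * (1 + 0.05 * stats::rnorm(length(sc$mu_a_l1)))
  noisy2 <- sc$mu_a_l2 * (1 + 0.05 * stats::rnorm(length(sc$mu_a_l2)))
  cmn <- unmix_two_wavelength(noisy1, noisy2, 750, 850)
  err <- abs(cmn$so2 - sc$so2_true)[cmn$mask]
  expect_lt(stats::median(err), 0.05)
  # deterministic under a fixed seed
  sc2 <- make_oxygenation_scene(n = 60, seed = 3)
  expect_identical(sc2$so2_true, sc$so2_true)
})

test_that("rasterization approaches analytic volumes and stays deterministic", {
  sp <- phantom_spec(
    list(absorber_primitive("sphere", center = c(0, 0, 2),
                            diameter_um = 1000)),
    grid = cartesian_grid(c(4, 4, 4), 0.02))
  ras <- rasterize_phantom(sp)
  vol <- sum(ras$mu_a > 0) * 0.02^3
  expect_equal(vol / ((4 / 3) * pi * 0.5^3), 1, tolerance = 0.05)
  coarse <- rasterize_phantom(
    phantom_spec(sp$primitives, grid = cartesian_grid(c(4, 4, 4), 0.05)))
  vol_c <- sum(coarse$mu_a > 0) * 0.05^3
  expect_lt(abs(vol / ((4 / 3) * pi * 0.5^3) - 1),
            abs(vol_c / ((4 / 3) * pi * 0.5^3) - 1) + 0.02)
  expect_identical(rasterize_phantom(sp)$mu_a, ras$mu_a)
  empty <- phantom_spec(list(), grid = cartesian_grid(c(4, 4, 4), 0.1))
  expect_true(all(rasterize_phantom(empty)$mu_a == 0))
  out <- phantom_spec(
    list(absorber_primitive("sphere", center = c(50, 0, 2),
                            diameter_um = 100)),
    grid = cartesian_grid(c(4, 4, 4), 0.1))
  expect_error(rasterize_phantom(out), "outside")
})
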