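test_that("absorption from concentrations is linear in each chromophore", {
  tab <- read_extinction_table()
  expect_equal(absorption_from_concentrations(800, 0, 0, tab), 0)
  e <- pasim:::extinction_at(tab, 750)
  expect_equal(absorption_from_concentrations(750, 2e-3, 0, tab),
               2e-3 * e[["eps_hbo2"]])
  expect_equal(absorption_from_concentrations(750, 1e-3, 3e-3, tab),
               absorption_from_concentrations(750, 1e-3, 0, tab) +
                 absorption_from_concentrations(750, 0, 3e-3, tab))
  expect_error(absorption_from_concentrations(500, 1, 1, tab), "range")
})

test_that("two-wavelength unmixing inverts synthetic pixels to machine precision", {
  tab <- read_extinction_table()
  set.seed(42)
  n <- 100
  hbo2 <- matrix(stats::runif(n * n, 0.2, 1.5), n, n)
  hb <- matrix(stats::runif(n * n, 0.1, 1.0), n, n)
  i1 <- absorption_from_concentrations(750, hbo2, hb, tab)
  i2 <- absorption_from_concentrations(850, hbo2, hb, tab)
  cm <- unmix_two_wavelength(i1, i2, 750, 850, tab)
  expect_lt(max(abs(cm$hbo2 - hbo2)) / max(hbo2), 1e-9)
  expect_lt(max(abs(cm$hb - hb)) / max(hb), 1e-9)
  expect_equal(cm$hbt, cm$hbo2 + cm$hb)
  expect_true(all(cm$mask))
  expect_true(all(cm$so2 >= 0 & cm$so2 <= 1))
  # pure HbO2 -> SO2 = 1 exactly
  pure <- unmix_two_wavelength(
    absorption_from_concentrations(750, hbo2, 0 * hb, tab),
    absorption_from_concentrations(850, hbo2, 0 * hb, tab), 750, 850, tab)
  expect_equal(max(abs(pure$so2 - 1)), 0, tolerance = 1e-9)
  expect_error(unmix_two_wavelength(i1, i2, 750, 750, tab), "singular")
  expect_error(unmix_two_wavelength(i1[1:10, ], i2, 750, 850, tab),
               "shape")
})

test_that("unmixing commutes with a common intensity scale", {
  tab <- read_extinction_table()
  set.seed(7)
  i1 <- matrix(stats::runif(400, 0.5, 2), 20, 20)
  i2 <- matrix(stats::runif(400, 0.5, 2), 20, 20)
  a <- unmix_two_wavelength(i1, i2, 750, 850, tab)
  b <- unmix_two_wavelength(3 * i1, 3 * i2, 750, 850, tab)
  expect_equal(b$hbt, 3 * a$hbt, tolerance = 1e-12)
  expect_equal(b$so2[a$mask & b$mask], a$so2[a$mask & b$mask],
               tolerance = 1e-12)
})

test_that("implausible pixels are masked, slight excursions clipped", {
  tab <- read_extinction_table()
  # a pixel with strongly negative implied HbO2: i1 >> i2 at 750/850
  cm <- unmix_two_wavelength(matrix(10), matrix(0.1), 750, 850, tab)
  expect_false(cm$mask[1])
  expect_true(cm$so2[1] %in% c(0, 1) || is.na(cm$so2[1]))
})

test_that("the CBV proxy normalizes to the reference mean and scales", {
  img <- matrix(3, 10, 10)
  expect_true(all(cbv_proxy(img) == 1))
  # against a fixed baseline scale, halved intensity halves the proxy
  expect_equal(cbv_proxy(img / 2, reference_mean = mean(img)),
               cbv_proxy(img) / 2)
  expect_error(cbv_proxy(img, reference = img > 5), "reference")
  # occlusion phantom: CBV drop confined to the occluded branch when the
  # two maps share the baseline normalization
  base <- make_vessel_scene(occluded = FALSE)
  occ <- make_vessel_scene(occluded = TRUE)
  top_b <- apply(rasterize_phantom(base$spec)$mu_a, c(1, 2), max)
  top_o <- apply(rasterize_phantom(occ$spec)$mu_a, c(1, 2), max)
  m0 <- mean(top_b[top_b > 0])
  dcb <- cbv_proxy(top_b, reference_mean = m0) -
    cbv_proxy(top_o, reference_mean = m0)
  changed <- abs(dcb) > 1e-6
  expect_true(any(changed))
  expect_true(all(changed[!occ$change_mask] == FALSE))
})

test_that("wavelength balancing returns unity for identical media and compensates", {
  grid <- small_grid()
  m1 <- lipofundin_1pct()
  f <- wavelength_intensity_balance(m1, m1, depth = 10,
                                    geom = small_geom(), grid = grid)
  expect_equal(f, 1, tolerance = 1e-9)
  m_abs <- optical_medium(0.08, 6.31, 0, 1.35)  # more absorbing "750 nm" medium
  f2 <- wavelength_intensity_balance(m_abs, m1, depth = 10,
                                     geom = small_geom(), grid = grid)
  expect_gt(f2, 1)
  # applying the factor equalizes the delivered fluence (linearity closure)
  phi1 <- fluence_at_depth(
    solve_fluence(m_abs, pulse_profile(Wp = 20 * f2), small_geom(), grid), 10)
  phi2 <- fluence_at_depth(
    solve_fluence(m1, pulse_profile(Wp = 20), small_geom(), grid), 10)
  expect_equal(phi1 / phi2, 1, tolerance = 1e-6)
})
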