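test_that("impulse response is centered at f_c with the stated -6 dB width", {
  arr <- default_array()
  dt <- 1 / 4000                       # us; heavily oversampled
  tt <- seq(-1, 1, by = dt)
  p <- transducer_impulse_response(arr, tt)
  expect_equal(max(p), 1, tolerance = 1e-6)
  # pulse is time-limited well under a microsecond
  expect_lt(max(abs(p[abs(tt) > 0.4])), 1e-10)
  np <- 2^17                           # zero-pad for fine spectral sampling
  sp <- Mod(stats::fft(c(p, rep(0, np - length(p)))))
  f <- (seq_len(np) - 1) / (np * dt)   # MHz
  keep <- f < 50
  sp <- sp[keep]; f <- f[keep]
  expect_equal(f[which.max(sp)], arr$center_frequency, tolerance = 0.02)
  half <- max(sp) * 10^(-6 / 20)
  above <- range(f[sp >= half])
  expect_equal(diff(above) / arr$center_frequency, 0.67, tolerance = 0.015)
})

test_that("RF forward model is geometric, linear and scales with reflectivity", {
  arr <- default_array()
  rf1 <- simulate_point_scatterer_rf(arr, point_scene(0, 10))
  # earliest arrival on the centermost elements
  first_idx <- apply(abs(rf1$rf) > 1e-3 * max(abs(rf1$rf)), 1,
                     function(v) which(v)[1])
  expect_equal(first_idx[64], min(first_idx))
  expect_equal(first_idx[65], min(first_idx))
  expect_gt(first_idx[1], first_idx[64])
  rf_a <- simulate_point_scatterer_rf(arr, point_scene(-1, 8))
  rf_b <- simulate_point_scatterer_rf(arr, point_scene(2, 12))
  rf_ab <- simulate_point_scatterer_rf(arr,
                                       point_scene(c(-1, 2), c(8, 12)))
  n <- min(ncol(rf_a$rf), ncol(rf_b$rf), ncol(rf_ab$rf))
  expect_lt(max(abs(rf_ab$rf[, 1:n] - rf_a$rf[, 1:n] - rf_b$rf[, 1:n])),
            1e-10 * max(abs(rf_ab$rf)))
  rf2 <- simulate_point_scatterer_rf(arr, point_scene(0, 10,
                                                      reflectivity = 2))
  expect_equal(rf2$rf, 2 * rf1$rf, tolerance = 1e-12)
  expect_error(simulate_point_scatterer_rf(arr, point_scene(0, 25)),
               "outside")
})

test_that("beamformed peak lands on the scatterer and translates with it", {
  arr <- default_array()
  m1 <- psf_at(arr, 0, 10)
  expect_lt(abs(m1$peak_x_mm - 0), 0.01)
  expect_lt(abs(m1$peak_z_mm - 10), 0.02)
  m2 <- psf_at(arr, 1, 10)
  expect_equal(m2$peak_x_mm - m1$peak_x_mm, 1, tolerance = 0.01)
  # an empty scene reconstructs to zero
  rf0 <- simulate_point_scatterer_rf(arr, point_scene(numeric(0),
                                                      numeric(0)))
  img0 <- das_beamform(rf0, arr, xlim = c(-1, 1), zlim = c(9, 11),
                       dx = 0.05, dz = 0.05)
  expect_true(all(img0$image == 0))
})

test_that("FWHM measurement matches the Gaussian closed form and is scale-free", {
  x <- seq(-1, 1, by = 0.005)
  z <- seq(9, 11, by = 0.005)
  sigma_x <- 0.1; sigma_z <- 0.05
  img <- structure(list(
    image = exp(-outer((z - 10)^2 / (2 * sigma_z^2),
                       (x - 0)^2 / (2 * sigma_x^2), `+`)),
    x = x, z = z, mode = "synthetic"), class = "beamformed_image")
  m <- measure_fwhm(img)
  expect_equal(m$lateral_fwhm_um, 2.3548 * sigma_x * 1000, tolerance = 0.02)
  expect_equal(m$axial_fwhm_um, 2.3548 * sigma_z * 1000, tolerance = 0.02)
  img2 <- img; img2$image <- img$image * 7.3
  m2 <- measure_fwhm(img2)
  expect_equal(m2$lateral_fwhm_um, m$lateral_fwhm_um)
  flat <- img; flat$image <- matrix(1, length(z), length(x))
  expect_error(measure_fwhm(flat), "half-maximum")
})

test_that("axial widths follow the pulse length with the c/2 round-trip scale", {
  arr <- default_array()
  c_mmus <- arr$sound_speed / 1000
  env_fwhm_us <- 2.3548 * pasim:::pulse_sigma_us(arr)
  pe <- psf_at(arr, 0, 10, mode = "pulse_echo")
  ow <- psf_at(arr, 0, 10, mode = "one_way")
  want_pe <- env_fwhm_us * sqrt(2) * c_mmus / 2 * 1000  # two-way band, c/2
  want_ow <- env_fwhm_us * c_mmus * 1000                # one-way band, c
  expect_equal(pe$axial_fwhm_um / want_pe, 1, tolerance = 0.1)
  expect_equal(ow$axial_fwhm_um / want_ow, 1, tolerance = 0.1)
})
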