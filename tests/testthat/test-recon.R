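test_that("stacking validates shapes and keeps values", {
  s1 <- matrix(1:12, 3, 4)
  st <- stack_bscans(list(s1), y_step = 0.05)
  expect_equal(dim(st$volume), c(3, 4, 1))
  expect_equal(st$volume[, , 1], s1)
  z0 <- stack_bscans(replicate(5, matrix(0, 3, 4), simplify = FALSE))
  expect_true(all(z0$volume == 0))
  expect_error(stack_bscans(list(s1, matrix(0, 2, 2))), "same shape")
  expect_error(stack_bscans(list(s1), y_step = 0), "y_step")
})

test_that("volume TIFF round-trips exactly for grid-representable data", {
  # multiples of 1/255 sit exactly on the codec's quantization grid
  vals <- array(as.numeric(sample(0:255, 10 * 12 * 4, replace = TRUE)) / 255,
                dim = c(10, 12, 4))
  vals[1] <- 1  # pin the power-of-two scale at unity
  st <- stack_bscans(vals, y_step = 0.05, x = seq_len(12), z = seq_len(10))
  p <- withr::local_tempfile(fileext = ".tif")
  write_volume_tiff(st, p)
  st2 <- read_volume_tiff(p)
  expect_identical(st2$volume, st$volume)
  expect_equal(st2$y, st$y)
})

test_that("MIP equals the brute-force per-line maximum on random volumes", {
  set.seed(11)
  st <- stack_bscans(array(stats::runif(8 * 8 * 8), c(8, 8, 8)),
                     y_step = 0.1)
  v <- st$volume
  top <- mip_project(st, "Z")
  side <- mip_project(st, "X")
  front <- mip_project(st, "Y")
  brute_top <- matrix(0, 8, 8); brute_side <- matrix(0, 8, 8)
  brute_front <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    brute_top[i, j] <- max(v[, i, j])    # along z for column (x=i, y=j)
    brute_side[i, j] <- max(v[i, , j])   # along x
    brute_front[i, j] <- max(v[i, j, ])  # along y
  }
  expect_identical(top$image, brute_top)
  expect_identical(side$image, brute_side)
  expect_identical(front$image, brute_front)
  # constant volumes project to the constant
  stc <- stack_bscans(array(3, c(4, 4, 4)))
  expect_true(all(mip_project(stc, "Z")$image == 3))
})

test_that("C-scan slices extract planes and reduce to the MIP at full range", {
  set.seed(12)
  st <- stack_bscans(array(stats::runif(10 * 6 * 4), c(10, 6, 4)),
                     y_step = 0.05, z = seq(8, 12.5, by = 0.5))
  cs <- extract_cscan_slices(st, depths = c(8, 10))
  expect_equal(cs$slices[[1]], st$volume[1, , ])
  expect_equal(cs$slices[[2]], st$volume[which.min(abs(st$z - 10)), , ])
  full <- extract_cscan_slices(st, depths = mean(range(st$z)),
                               thickness = diff(range(st$z)) + 1)
  expect_identical(full$slices[[1]], mip_project(st, "Z")$image)
  expect_error(extract_cscan_slices(st, depths = 40), "range")
})

test_that("depth coding records argmax depth and windowed MIP brightness", {
  st <- stack_bscans(array(0, c(10, 5, 5)), y_step = 0.05,
                     z = seq(8, 12.5, by = 0.5))
  v <- st$volume
  v[3, 2, 2] <- 1        # impulse at z = 9
  v[7, 4, 4] <- 2        # impulse at z = 11
  st$volume <- v
  dc <- depth_color_code(st, z_window = c(8, 12.5))
  expect_equal(dc$depth[2, 2], 9)
  expect_equal(dc$depth[4, 4], 11)
  expect_identical(dc$intensity, mip_project(st, "Z")$image)
  win <- depth_color_code(st, z_window = c(8, 10))
  sub <- stack_bscans(st$volume[st$z <= 10, , , drop = FALSE],
                      y_step = 0.05)
  expect_identical(win$intensity, mip_project(sub, "Z")$image)
  expect_error(depth_color_code(st, z_window = c(20, 30)), "window")
})

test_that("overlay thresholds select the expected PA pixels", {
  us <- matrix(stats::runif(64), 8, 8)
  pa <- matrix(0, 8, 8); pa[3, 4] <- 1; pa[6, 6] <- 0.5; pa[1, 1] <- 0.05
  ov0 <- coregister_overlay(us, pa, threshold_db = 0)
  expect_equal(sum(ov0$overlay_mask), 1)
  expect_true(ov0$overlay_mask[3, 4])
  ov_all <- coregister_overlay(us, pa, threshold_db = -Inf)
  expect_true(all(ov_all$overlay_mask))
  ov <- coregister_overlay(us, pa, threshold_db = -20)
  expect_true(ov$overlay_mask[6, 6])
  expect_false(ov$overlay_mask[1, 1])
  expect_identical(ov$us, us)  # base image untouched below threshold
  expect_error(coregister_overlay(us[1:4, ], pa), "geometry")
})
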