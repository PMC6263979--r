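#' Measure the point-spread function FWHM
#'
#' Finds the dominant peak of an envelope image and measures the full
#' width at half maximum along the axial and lateral lines through it,
#' interpolating linearly between samples at the half-maximum crossings.
#'
#' @param img A `beamformed_image` (linear envelope).
#' @return A `psf_measurement`: list with `axial_fwhm_um`,
#'   `lateral_fwhm_um` and the peak position (`peak_x_mm`, `peak_z_mm`).
#' @export
measure_fwhm <- function(img) {
  stopifnot(inherits(img, "beamformed_image"))
  im <- img$image
  ip <- which(im == max(im), arr.ind = TRUE)[1, ]
  ax <- half_max_width(img$z, im[, ip[2]]) * 1000
  lat <- half_max_width(img$x, im[ip[1], ]) * 1000
  if (is.na(ax) || is.na(lat)) {
    stop("no half-maximum crossing inside the image", call. = FALSE)
  }
  structure(list(axial_fwhm_um = ax, lateral_fwhm_um = lat,
                 peak_x_mm = img$x[ip[2]], peak_z_mm = img$z[ip[1]]),
            class = "psf_measurement")
}

#' @export
print.psf_measurement <- function(x, ...) {
  cat(sprintf("<psf_measurement> axial %.1f um, lateral %.1f um at (%.2f, %.2f) mm\n",
              x$axial_fwhm_um, x$lateral_fwhm_um, x$peak_x_mm, x$peak_z_mm))
  invisible(x)
}

#' Simulate, beamform and measure one point-spread function
#'
#' One cycle of the PSF study: a single ideal scatterer at `(x, z)`,
#' plane-wave pulse-echo acquisition, delay-and-sum reconstruction of a
#' small region of interest around the point, and FWHM measurement.
#'
#' @param array A [linear_array()].
#' @param x,z Scatterer position (mm).
#' @param mode `"pulse_echo"` or `"one_way"`.
#' @param roi_half Half-size of the reconstructed region (mm).
#' @param dx,dz Reconstruction pixel (mm).
#' @param ... Passed to [das_beamform()] (`f_number`, `apodization`).
#' @return A `psf_measurement`.
#' @export
psf_at <- function(array, x = 0, z = 10, mode = "pulse_echo",
                   roi_half = 0.8, dx = 0.005, dz = 0.005, ...) {
  rf <- simulate_point_scatterer_rf(array, point_scene(x, z), mode = mode)
  img <- das_beamform(rf, array,
                      xlim = c(x - roi_half, x + roi_half),
                      zlim = c(max(dz, z - roi_half), z + roi_half),
                      dx = dx, dz = dz, ...)
  measure_fwhm(img)
}

#' Sweep the PSF over the imaging area
#'
#' Repeats simulate -> beamform -> measure over a lateral x depth grid and
#' tabulates the axial and lateral FWHM maps.
#'
#' @param array A [linear_array()].
#' @param x_range,z_range Sweep extents (mm), defaults -6..6 and 3..15.
#' @param step Grid step (mm, default 1).
#' @param ... Passed to [psf_at()].
#' @return A tibble with columns `x_mm`, `z_mm`, `axial_fwhm_um`,
#'   `lateral_fwhm_um`.
#' @export
psf_map_sweep <- function(array, x_range = c(-6, 6), z_range = c(3, 15),
                          step = 1, ...) {
  pos <- tidyr::expand_grid(x_mm = seq(x_range[1], x_range[2], by = step),
                            z_mm = seq(z_range[1], z_range[2], by = step))
  res <- purrr::pmap_dfr(pos, function(x_mm, z_mm) {
    m <- psf_at(array, x_mm, z_mm, ...)
    tibble::tibble(axial_fwhm_um = m$axial_fwhm_um,
                   lateral_fwhm_um = m$lateral_fwhm_um)
  })
  dplyr::bind_cols(pos, res)
}

#' Two-point resolvability at a given depth and separation
#'
#' Places two equal scatterers separated laterally, reconstructs, and
#' extracts the lateral profile through the peak depth.  The pair is
#' "resolvable" when the profile has two local maxima and the valley
#' between the two highest is at least `dip_db` below the lower peak
#' (default 3 dB; set 0 for any local-maximum pair).
#'
#' @param array A [linear_array()].
#' @param depth Depth (mm).
#' @param separation Lateral separation (micrometers).
#' @param dip_db Required valley depth (dB).
#' @param dx Lateral pixel (mm).
#' @param ... Passed to [das_beamform()].
#' @return List with `resolvable`, `dip_db_measured` and the lateral
#'   `profile` tibble.
#' @export
two_point_resolvability <- function(array, depth, separation, dip_db = 3,
                                    dx = 0.005, ...) {
  if (separation <= 0) stop("`separation` must be > 0", call. = FALSE)
  s_mm <- separation / 1000
  scene <- point_scene(c(-s_mm / 2, s_mm / 2), c(depth, depth))
  rf <- simulate_point_scatterer_rf(array, scene)
  margin <- 0.6
  img <- das_beamform(rf, array,
                      xlim = c(-s_mm / 2 - margin, s_mm / 2 + margin),
                      zlim = c(depth - 0.6, depth + 0.6),
                      dx = dx, dz = 0.01, ...)
  iz <- which(img$image == max(img$image), arr.ind = TRUE)[1, 1]
  prof <- img$image[iz, ]
  res <- classify_two_peaks(prof, dip_db)
  list(resolvable = res$resolvable, dip_db_measured = res$dip,
       profile = tibble::tibble(x_mm = img$x, envelope = prof))
}

# local-maxima / valley classification of a lateral profile; only maxima
# above `floor` (fraction of the global peak, default -20 dB) count, which
# excludes coherent interference fringes from the peak census
classify_two_peaks <- function(prof, dip_db, floor = 0.1) {
  n <- length(prof)
  is_max <- which(prof[2:(n - 1)] > prof[1:(n - 2)] &
                    prof[2:(n - 1)] >= prof[3:n]) + 1
  is_max <- is_max[prof[is_max] > floor * max(prof)]
  if (length(is_max) < 2) {
    return(list(resolvable = FALSE, dip = 0, n_maxima = length(is_max)))
  }
  top2 <- is_max[order(prof[is_max], decreasing = TRUE)[1:2]]
  lo <- min(top2); hi <- max(top2)
  valley <- min(prof[lo:hi])
  lower_peak <- min(prof[top2])
  dip <- 20 * log10(lower_peak / max(valley, .Machine$double.eps))
  list(resolvable = dip >= dip_db, dip = dip, n_maxima = length(is_max))
}

#' Smallest resolvable two-point separation
#'
#' Sweeps the separation (default 100 to 400 micrometers in 10-um steps)
#' at a fixed depth and reports the first separation classified
#' resolvable; all larger separations in the sweep are reported with it
#' so monotonicity can be inspected.
#'
#' @inheritParams two_point_resolvability
#' @param separations Sweep values (micrometers).
#' @return List with `min_separation_um` (`Inf` when nothing in the sweep
#'   resolves) and the sweep tibble (`separation_um`, `resolvable`,
#'   `dip_db`).
#' @export
min_resolvable_separation <- function(array, depth,
                                      separations = seq(100, 400, by = 10),
                                      dip_db = 3, ...) {
  rows <- purrr::map_dfr(separations, function(s) {
    r <- two_point_resolvability(array, depth, s, dip_db = dip_db, ...)
    tibble::tibble(separation_um = s, resolvable = r$resolvable,
                   dip_db = r$dip_db_measured)
  })
  first <- which(rows$resolvable)[1]
  list(min_separation_um = if (is.na(first)) Inf else rows$separation_um[first],
       sweep = rows)
}
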