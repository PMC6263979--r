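#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a PSF measurement
#' @param x A `psf_measurement`.
#' @param ... Unused.
#' @return One-row tibble with the FWHM values and peak position.
#' @method tidy psf_measurement
#' @export
tidy.psf_measurement <- function(x, ...) {
  tibble::tibble(axial_fwhm_um = x$axial_fwhm_um,
                 lateral_fwhm_um = x$lateral_fwhm_um,
                 peak_x_mm = x$peak_x_mm, peak_z_mm = x$peak_z_mm)
}

#' @rdname tidy.psf_measurement
#' @export
glance.psf_measurement <- tidy.psf_measurement

#' Tidy a fluence field into a depth profile
#' @param x A `fluence_field`.
#' @param ... Passed to [fluence_depth_profile()].
#' @return Tibble with `depth_mm`, `fluence`.
#' @method tidy fluence_field
#' @export
tidy.fluence_field <- function(x, ...) {
  fluence_depth_profile(x, ...)
}

#' One-line summary of a fluence solution
#' @param x A `fluence_field`.
#' @param ... Unused.
#' @return One-row tibble: mode, cell count, peak fluence, fluence at
#'   10 mm on the midline.
#' @method glance fluence_field
#' @export
glance.fluence_field <- function(x, ...) {
  tibble::tibble(mode = x$mode, n_cells = length(x$values),
                 max_fluence = max(x$values),
                 fluence_10mm = fluence_at_depth(x, 10))
}

#' Tidy a chromophore map into a long pixel table
#' @param x A `chromophore_map`.
#' @param ... Unused.
#' @return Tibble with pixel indices, `hbo2`, `hb`, `hbt`, `so2`,
#'   `valid`.
#' @method tidy chromophore_map
#' @export
tidy.chromophore_map <- function(x, ...) {
  d <- dim(x$hbt)
  tibble::tibble(row = rep(seq_len(d[1]), d[2]),
                 col = rep(seq_len(d[2]), each = d[1]),
                 hbo2 = as.numeric(x$hbo2), hb = as.numeric(x$hb),
                 hbt = as.numeric(x$hbt), so2 = as.numeric(x$so2),
                 valid = as.logical(x$mask))
}

#' One-line summary of a chromophore map
#' @param x A `chromophore_map`.
#' @param ... Unused.
#' @return One-row tibble: valid fraction, median/mean SO2 over the
#'   valid mask, total HbT.
#' @method glance chromophore_map
#' @export
glance.chromophore_map <- function(x, ...) {
  tibble::tibble(n_pixels = length(x$hbt), valid_fraction = mean(x$mask),
                 median_so2 = stats::median(x$so2[x$mask]),
                 mean_so2 = mean(x$so2[x$mask]),
                 mean_hbt = mean(x$hbt[x$mask]))
}

#' Tidy a pressure field observation trace
#' @param x A `pressure_field`.
#' @param ... Unused.
#' @return Tibble with `time_ns`, `p_pa`.
#' @method tidy pressure_field
#' @export
tidy.pressure_field <- function(x, ...) {
  tibble::tibble(time_ns = x$time_ns, p_pa = x$p_obs)
}

#' One-line summary of a pressure field
#' @param x A `pressure_field`.
#' @param ... Unused.
#' @return One-row tibble: peak |p|, its time, observation radius.
#' @method glance pressure_field
#' @export
glance.pressure_field <- function(x, ...) {
  i <- which.max(abs(x$p_obs))
  tibble::tibble(peak_pressure_pa = abs(x$p_obs[i]),
                 peak_time_ns = x$time_ns[i], r_obs_um = x$r_obs_um)
}

#' Tidy a MIP image into a long pixel table
#' @param x A `mip_image`.
#' @param ... Unused.
#' @return Tibble with the two axis coordinates and `intensity`.
#' @method tidy mip_image
#' @export
tidy.mip_image <- function(x, ...) {
  d <- dim(x$image)
  out <- tibble::tibble(a1 = rep(x$a1, d[2]),
                        a2 = rep(x$a2, each = d[1]),
                        intensity = as.numeric(x$image))
  names(out)[1:2] <- x$names
  out
}

#' Tidy a beamformed image into a long pixel table
#' @param x A `beamformed_image`.
#' @param ... Unused.
#' @return Tibble with `x_mm`, `z_mm`, `envelope`.
#' @method tidy beamformed_image
#' @export
tidy.beamformed_image <- function(x, ...) {
  tibble::tibble(x_mm = rep(x$x, each = length(x$z)),
                 z_mm = rep(x$z, length(x$x)),
                 envelope = as.numeric(x$image))
}
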