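#' Plot a beamformed image
#'
#' Log-compressed envelope display with physical axes and a dB colorbar.
#'
#' @param object A `beamformed_image`.
#' @param dynamic_range Display range (dB, default 40).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot beamformed_image
#' @export
autoplot.beamformed_image <- function(object, dynamic_range = 40, ...) {
  db <- log_compress(object, dynamic_range)
  df <- tidy.beamformed_image(db)
  names(df)[3] <- "dB"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_mm, y = .data$z_mm,
                                   fill = .data$dB)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "magma", name = "dB") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "lateral (mm)", y = "depth (mm)") +
    ggplot2::theme_minimal()
}

#' Plot a maximum intensity projection
#'
#' @param object A `mip_image`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mip_image
#' @export
autoplot.mip_image <- function(object, ...) {
  df <- tidy.mip_image(object)
  nm <- names(df)[1:2]
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[nm[2]]], y = .data[[nm[1]]],
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "magma") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = object$view) +
    ggplot2::theme_minimal()
}

#' Plot a depth-coded projection
#'
#' Hue encodes the depth of the brightest voxel within the window;
#' brightness encodes its intensity (the windowed MIP).
#'
#' @param object A `depth_coded_image`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot depth_coded_image
#' @export
autoplot.depth_coded_image <- function(object, ...) {
  zw <- object$z_window
  hue <- (object$depth - zw[1]) / max(zw[2] - zw[1], .Machine$double.eps)
  val <- object$intensity / max(object$intensity, .Machine$double.eps)
  cols <- grDevices::hsv(h = 0.75 * pmin(pmax(hue, 0), 1), s = 1,
                         v = pmin(pmax(val, 0), 1))
  df <- tibble::tibble(x = rep(object$x, length(object$y)),
                       y = rep(object$y, each = length(object$x)),
                       col = cols)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$y, y = .data$x)) +
    ggplot2::geom_raster(fill = df$col) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "scan (mm)", y = "lateral (mm)",
                  title = sprintf("depth-coded %.1f-%.1f mm", zw[1], zw[2])) +
    ggplot2::theme_minimal()
}

#' Plot SO2 or HbT maps from a chromophore map
#'
#' @param object A `chromophore_map`.
#' @param what `"so2"` (default) or `"hbt"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot chromophore_map
#' @export
autoplot.chromophore_map <- function(object, what = c("so2", "hbt"), ...) {
  what <- match.arg(what)
  df <- tidy.chromophore_map(object)
  df$value <- df[[what]]
  df$value[!df$valid] <- NA
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(
      option = if (what == "so2") "turbo" else "magma",
      limits = if (what == "so2") c(0, 1) else NULL, name = toupper(what)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot the midline slice of a fluence field
#'
#' @param object A `fluence_field` (steady).
#' @param log10_scale Show log10 fluence (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot of the y = 0 (x-z) mid-plane.
#' @method autoplot fluence_field
#' @export
autoplot.fluence_field <- function(object, log10_scale = TRUE, ...) {
  g <- object$grid
  jy <- which.min(abs(g$y))
  vals <- object$values
  if (object$mode == "transient") vals <- vals[, , , dim(vals)[4]]
  sl <- vals[, jy, ]
  df <- tibble::tibble(x = rep(g$x, length(g$z)),
                       z = rep(g$z, each = length(g$x)),
                       fluence = as.numeric(sl))
  if (log10_scale) df$fluence <- log10(pmax(df$fluence, max(df$fluence) * 1e-6))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z,
                                   fill = .data$fluence)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(
      name = if (log10_scale) "log10 fluence" else "fluence") +
    ggplot2::labs(x = "x (mm)", y = "depth (mm)") +
    ggplot2::theme_minimal()
}

#' Plot fluence design-sweep tables
#'
#' Depth profiles colored by the swept parameter (incident angle or arm
#' interval).
#'
#' @param sweep A tibble from [sweep_incident_angle()] or
#'   [sweep_arm_interval()].
#' @return A ggplot.
#' @export
plot_fluence_sweep <- function(sweep) {
  by <- intersect(c("angle_deg", "interval_mm"), names(sweep))[1]
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$depth_mm, y = .data$fluence,
                                      color = factor(.data[[by]]))) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "depth (mm)", y = "fluence (J/cm²)",
                  color = if (by == "angle_deg") "angle (deg)" else
                    "interval (mm)") +
    ggplot2::theme_minimal()
}

#' Plot PSF FWHM maps from a sweep table
#'
#' @param psf_map Tibble from [psf_map_sweep()].
#' @param which `"lateral"` (default) or `"axial"`.
#' @return A ggplot.
#' @export
plot_psf_map <- function(psf_map, which = c("lateral", "axial")) {
  which <- match.arg(which)
  col <- paste0(which, "_fwhm_um")
  ggplot2::ggplot(psf_map, ggplot2::aes(x = .data$x_mm, y = .data$z_mm,
                                        fill = .data[[col]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = paste(which, "FWHM (µm)")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "lateral (mm)", y = "depth (mm)") +
    ggplot2::theme_minimal()
}

#' Plot the US/PA overlay
#'
#' @param object An `overlay_image`.
#' @param dynamic_range US display range (dB).
#' @param ... Unused.
#' @return A ggplot: grayscale US with PA pixels above threshold in
#'   color.
#' @method autoplot overlay_image
#' @export
autoplot.overlay_image <- function(object, dynamic_range = 40, ...) {
  us <- object$us / max(object$us, .Machine$double.eps)
  us_db <- pmax(20 * log10(pmax(us, 1e-12)), -dynamic_range)
  d <- dim(us)
  df <- tibble::tibble(row = rep(seq_len(d[1]), d[2]),
                       col = rep(seq_len(d[2]), each = d[1]),
                       us_db = as.numeric(us_db),
                       pa = as.numeric(object$pa),
                       ov = as.logical(object$overlay_mask))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$us_db)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 name = "US (dB)") +
    ggplot2::geom_point(data = dplyr::filter(df, .data$ov),
                        ggplot2::aes(color = .data$pa), size = 0.3) +
    ggplot2::scale_color_viridis_c(option = "inferno", name = "PA") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
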