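#' Delay-and-sum beamforming
#'
#' Standard pixel-based delay-and-sum: for every pixel, element samples
#' are taken at the mode-appropriate delay (round trip with plane-wave
#' transmit for `pulse_echo`; one-way for `one_way`), with the receive
#' aperture dynamically limited to the requested f-number and optional
#' Hann apodization across the active aperture.  Element signals are
#' converted to their analytic form (FFT Hilbert transform) before
#' summation, so the output is a linear-scale envelope image; log
#' compression is applied only for display.
#'
#' @param rf An `rf_data` from [simulate_point_scatterer_rf()] (or any
#'   object with the same fields).
#' @param array A [linear_array()]; defaults to the one stored in `rf`.
#' @param xlim,zlim Image extent (mm), `c(min, max)`.
#' @param dx,dz Pixel size (mm).
#' @param f_number Receive f-number limiting the dynamic aperture
#'   (half-aperture = z / (2 f#)); default 1.
#' @param apodization `"hann"` (default) or `"none"` across the active
#'   aperture.
#' @return A `beamformed_image`: list with envelope matrix `image`
#'   (rows = depth, columns = lateral), axis vectors `x`, `z` (mm), the
#'   mode and beamforming settings.
#' @export
das_beamform <- function(rf, array = rf$array, xlim, zlim,
                         dx = 0.005, dz = 0.005,
                         f_number = 1, apodization = c("hann", "none")) {
  apodization <- match.arg(apodization)
  c_mmus <- array$sound_speed / 1000
  x <- seq(xlim[1], xlim[2], by = dx)
  z <- seq(zlim[1], zlim[2], by = dz)
  if (min(z) < 0) stop("image grid outside data support", call. = FALSE)
  nt <- ncol(rf$rf)
  dt <- 1 / rf$sample_rate
  max_t <- rf$start_time + (nt - 1) * dt
  # analytic signal per element (Hilbert via FFT along time)
  ana <- t(apply(rf$rf, 1, analytic_signal))
  acc <- .das_accumulate(Re(ana), Im(ana), element_positions(array),
                         x, z, c_mmus, dt, rf$start_time,
                         rf$mode == "pulse_echo",
                         f_number %||% 0, apodization == "hann")
  env <- sqrt(acc$re^2 + acc$im^2)
  structure(list(image = env, x = x, z = z, mode = rf$mode,
                 f_number = f_number, apodization = apodization),
            class = "beamformed_image")
}

# analytic signal of a real vector via the frequency-domain Hilbert method
analytic_signal <- function(v) {
  n <- length(v)
  V <- stats::fft(v)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(V * h, inverse = TRUE) / n
}

#' @export
print.beamformed_image <- function(x, ...) {
  cat(sprintf("<beamformed_image: %s> %d x %d px, x [%g, %g] mm, z [%g, %g] mm\n",
              x$mode, nrow(x$image), ncol(x$image),
              min(x$x), max(x$x), min(x$z), max(x$z)))
  invisible(x)
}

#' Log-compress an envelope image for display
#'
#' @param img A `beamformed_image`.
#' @param dynamic_range Display range in dB (default 40).
#' @return The image with `image` replaced by dB values clipped to
#'   `[-dynamic_range, 0]`.
#' @export
log_compress <- function(img, dynamic_range = 40) {
  m <- max(img$image)
  if (m <= 0) stop("empty image", call. = FALSE)
  db <- 20 * log10(pmax(img$image / m, 10^(-dynamic_range / 20 - 1)))
  img$image <- pmax(db, -dynamic_range)
  img$dynamic_range <- dynamic_range
  img
}
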