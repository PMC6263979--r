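#' Linear transducer array description
#'
#' Geometry and band of the receiving/transmitting linear array.  The
#' defaults describe a 128-element, 0.10-mm-pitch array centered at
#' 18.5 MHz with a 67% two-sided -6 dB fractional bandwidth, sampled at
#' 62.5 MHz.
#'
#' @param n_elements Number of elements (>= 2).
#' @param pitch Element pitch (mm).
#' @param center_frequency Center frequency (MHz).
#' @param fractional_bandwidth Two-sided -6 dB fractional bandwidth (%).
#' @param element_width Element width (mm), default `0.9 * pitch`.
#' @param sound_speed Speed of sound (m/s), default 1540.
#' @param sample_rate Sampling rate (MHz); must exceed twice the upper
#'   band edge.
#' @return A `linear_array` object.
#' @export
linear_array <- function(n_elements = 128, pitch = 0.10,
                         center_frequency = 18.5, fractional_bandwidth = 67,
                         element_width = 0.9 * pitch, sound_speed = 1540,
                         sample_rate = 62.5) {
  if (n_elements < 2) stop("`n_elements` must be >= 2", call. = FALSE)
  if (pitch <= 0) stop("`pitch` must be > 0", call. = FALSE)
  if (fractional_bandwidth <= 0 || fractional_bandwidth >= 200) {
    stop("`fractional_bandwidth` must lie in (0, 200)", call. = FALSE)
  }
  if (sample_rate <= 2 * center_frequency * (1 + fractional_bandwidth / 200)) {
    stop("`sample_rate` must exceed twice the upper band edge", call. = FALSE)
  }
  structure(list(n_elements = as.integer(n_elements), pitch = pitch,
                 center_frequency = center_frequency,
                 fractional_bandwidth = fractional_bandwidth,
                 element_width = element_width, sound_speed = sound_speed,
                 sample_rate = sample_rate),
            class = "linear_array")
}

#' Element x-positions (mm), centered on 0
#' @param array A [linear_array()].
#' @return Numeric vector of element centers.
#' @export
element_positions <- function(array) {
  (seq_len(array$n_elements) - (array$n_elements + 1) / 2) * array$pitch
}

#' Transducer impulse response
#'
#' Gaussian-enveloped sinusoid at the center frequency whose two-sided
#' -6 dB spectral width equals the fractional bandwidth, unit peak:
#' `s(t) = exp(-t^2 / (2 sigma^2)) cos(2 pi f_c t)` with
#' `sigma = 0.3741 / (FBW * f_c)` (the -6 dB amplitude points of the
#' Gaussian spectrum sit `0.3741 / sigma` apart).
#'
#' @param array A [linear_array()].
#' @param t Time axis in microseconds (zero-centered for a symmetric
#'   pulse).
#' @return Waveform values at `t`.
#' @export
transducer_impulse_response <- function(array, t) {
  fc <- array$center_frequency                   # MHz, t in us
  bw <- array$fractional_bandwidth / 100 * fc    # MHz
  sigma <- sqrt(2 * log(10^(6 / 20))) / pi / bw  # = 0.37413 / bw
  exp(-t^2 / (2 * sigma^2)) * cos(2 * pi * fc * t)
}

# pulse envelope sigma in us
pulse_sigma_us <- function(array) {
  bw <- array$fractional_bandwidth / 100 * array$center_frequency
  sqrt(2 * log(10^(6 / 20))) / pi / bw
}

#' Point scatterer scene
#'
#' @param x Lateral positions (mm, from array center).
#' @param z Depths (mm, > 0).
#' @param reflectivity Non-negative amplitudes (recycled).
#' @return A tibble with class `point_scene`.
#' @export
point_scene <- function(x, z, reflectivity = 1) {
  if (any(z <= 0)) stop("scatterer depth must be > 0", call. = FALSE)
  if (any(reflectivity < 0)) stop("reflectivity must be >= 0", call. = FALSE)
  out <- tibble::tibble(x = x, z = z,
                        reflectivity = rep_len(reflectivity, length(x)))
  class(out) <- c("point_scene", class(out))
  out
}
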