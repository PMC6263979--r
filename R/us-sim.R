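#' Simulate per-element RF signals from point scatterers
#'
#' Linear forward model: each element records the sum over scatterers of
#' the band-limited pulse delayed by the propagation time, weighted by
#' reflectivity, hard-baffle element directivity
#' `sinc(pi w sin(theta) / lambda)` and spherical spreading `1/d`.
#' `pulse_echo` mode assumes plane-wave (flash) transmit, so the transmit
#' path is the depth `z` and the round-trip waveform is the transducer
#' band applied twice (envelope width `sigma sqrt(2)`); `one_way` mode
#' models a photoacoustic source received through the band once.
#'
#' @param array A [linear_array()].
#' @param scene A [point_scene()].  Scatterers must lie inside the
#'   imaging region (lateral -6.4..6.4 mm, depth 0..20 mm).
#' @param mode `"pulse_echo"` or `"one_way"`.
#' @return An `rf_data` object: matrix `rf` (elements x samples),
#'   `sample_rate` (MHz), `start_time` (us), `mode`, `array`.
#' @export
simulate_point_scatterer_rf <- function(array, scene,
                                        mode = c("pulse_echo", "one_way")) {
  mode <- match.arg(mode)
  stopifnot(inherits(array, "linear_array"))
  half_ap <- array$n_elements * array$pitch / 2
  if (any(abs(scene$x) > 6.4) || any(scene$z > 20) || any(scene$z <= 0)) {
    stop("scatterer outside the imaging region", call. = FALSE)
  }
  c_mmus <- array$sound_speed / 1000        # mm/us
  xe <- element_positions(array)
  dt <- 1 / array$sample_rate               # us
  sigma <- pulse_sigma_us(array) * if (mode == "pulse_echo") sqrt(2) else 1
  tx <- function(z) if (mode == "pulse_echo") z / c_mmus else 0
  max_delay <- if (nrow(scene) == 0) {
    40 / c_mmus
  } else {
    max(tx(scene$z) + (sqrt((max(abs(scene$x)) + half_ap)^2 +
                              max(scene$z)^2)) / c_mmus)
  }
  nt <- ceiling((max_delay + 8 * sigma) / dt) + 1L
  t_axis <- (seq_len(nt) - 1) * dt
  lambda <- c_mmus / array$center_frequency # mm
  fc <- array$center_frequency

  rf <- matrix(0, array$n_elements, nt)
  for (s in seq_len(nrow(scene))) {
    dxs <- scene$x[s] - xe
    d <- sqrt(dxs^2 + scene$z[s]^2)
    sin_th <- dxs / d
    arg <- pi * array$element_width * sin_th / lambda
    direc <- ifelse(abs(arg) < 1e-12, 1, sin(arg) / arg)
    delay <- tx(scene$z[s]) + d / c_mmus
    amp <- scene$reflectivity[s] * direc / d
    tt <- outer(delay, -t_axis, function(a, b) -(a + b))  # t - delay
    rf <- rf + amp * exp(-tt^2 / (2 * sigma^2)) * cos(2 * pi * fc * tt)
  }
  structure(list(rf = rf, sample_rate = array$sample_rate, start_time = 0,
                 mode = mode, array = array),
            class = "rf_data")
}

#' @export
print.rf_data <- function(x, ...) {
  cat(sprintf("<rf_data: %s> %d elements x %d samples at %g MHz\n",
              x$mode, nrow(x$rf), ncol(x$rf), x$sample_rate))
  invisible(x)
}
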