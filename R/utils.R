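`%||%` <- function(x, y) if (is.null(x)) y else x

# linear interpolation of the half-maximum crossing width of a sampled
# profile around its peak; returns NA when no crossing exists on a side
half_max_width <- function(x, y) {
  ip <- which.max(y)
  half <- y[ip] / 2
  left <- NA_real_
  if (ip > 1) {
    for (i in ip:2) {
      if (y[i - 1] <= half) {
        f <- (y[i] - half) / (y[i] - y[i - 1])
        left <- x[i] - f * (x[i] - x[i - 1])
        break
      }
    }
  }
  right <- NA_real_
  if (ip < length(y)) {
    for (i in ip:(length(y) - 1)) {
      if (y[i + 1] <= half) {
        f <- (y[i] - half) / (y[i] - y[i + 1])
        right <- x[i] + f * (x[i + 1] - x[i])
        break
      }
    }
  }
  right - left
}
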