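#' Write a volume or image to multi-page float TIFF
#'
#' Stores a numeric array as 32-bit TIFF pages (one page per final-axis
#' slice) together with a YAML sidecar (`<path>.yml`) carrying the
#' amplitude scale and axis metadata.  Samples are quantized to the
#' codec's 32-bit integer grid (relative step about 2e-10); normalized
#' values expressible as k / (2^32 - 1) -- which includes all multiples
#' of 1/255 -- round-trip bit-exactly.
#'
#' @param x A matrix, 3-D array, or [stack_bscans()] object.
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(x, path) {
  meta <- list()
  if (inherits(x, "bscan_stack")) {
    meta <- list(x = x$x, z = x$z, y_step = if (length(x$y) > 1) diff(x$y[1:2]) else 0.05)
    x <- x$volume
  }
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1))
  # power-of-two scale so the division itself is exact
  scale <- 2^ceiling(log2(max(x, 1e-300)))
  pages <- lapply(seq_len(dim(x)[3]), function(k) x[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  yaml::write_yaml(c(list(scale = scale, dim = dim(x)), meta),
                   paste0(path, ".yml"))
  invisible(path)
}

#' Read a volume written by [write_volume_tiff()]
#'
#' @param path The `.tif` path.
#' @param as_stack Return a [stack_bscans()] object when axis metadata is
#'   present (default `TRUE`).
#' @return A 3-D array or `bscan_stack`.
#' @export
read_volume_tiff <- function(path, as_stack = TRUE) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  # undo the codec's asymmetric quantization scales (stored with a
  # 2^32 - 1 quantum, decoded against 2^32)
  vol <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages))) *
    (2^32 / (2^32 - 1)) * meta$scale
  if (as_stack && !is.null(meta$x)) {
    return(stack_bscans(vol, y_step = meta$y_step, x = meta$x, z = meta$z))
  }
  vol
}

#' Export a sweep table to CSV
#'
#' @param tbl A tibble (e.g. from [sweep_incident_angle()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(tbl, path) {
  utils::write.csv(tbl, path, row.names = FALSE)
  invisible(path)
}
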