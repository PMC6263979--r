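#' Stack B-scans into a volume
#'
#' Collects ordered X-Z envelope images acquired while stepping the probe
#' along Y into a 3-D volume with axis metadata.
#'
#' @param slices A list of equally sized matrices (rows = depth z,
#'   columns = lateral x), or a 3-D array `[z, x, y]`.
#' @param y_step Elevation step between consecutive slices (mm,
#'   default 0.05).
#' @param x,z Optional axis vectors (mm); defaults are pixel indices.
#' @return A `bscan_stack`: list with `volume` (`[z, x, y]`), axis
#'   vectors `x`, `z`, `y`.
#' @export
stack_bscans <- function(slices, y_step = 0.05, x = NULL, z = NULL) {
  if (is.list(slices)) {
    dims <- vapply(slices, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
      stop("all slices must have the same shape", call. = FALSE)
    }
    volume <- array(unlist(slices), dim = c(dims[1, 1], dims[2, 1],
                                            length(slices)))
  } else {
    stopifnot(length(dim(slices)) == 3)
    volume <- slices
  }
  if (y_step <= 0) stop("`y_step` must be > 0", call. = FALSE)
  d <- dim(volume)
  structure(list(volume = volume,
                 z = z %||% seq_len(d[1]),
                 x = x %||% seq_len(d[2]),
                 y = (seq_len(d[3]) - 1) * y_step),
            class = "bscan_stack")
}

#' @export
print.bscan_stack <- function(x, ...) {
  d <- dim(x$volume)
  cat(sprintf("<bscan_stack> %d x %d px B-scans, %d slices (y step %g mm)\n",
              d[1], d[2], d[3], if (d[3] > 1) diff(x$y[1:2]) else NA))
  invisible(x)
}

#' Maximum intensity projection
#'
#' Projects the volume by taking, for every projection line, the maximum
#' intensity along the chosen axis.  Projecting along Z gives the
#' TopView (X-Y) image; along X the SideView (Y-Z); along Y a B-scan-like
#' X-Z composite.
#'
#' @param stack A [stack_bscans()] volume.
#' @param axis `"Z"`, `"X"` or `"Y"`.
#' @return A `mip_image`: list with matrix `image` and its two axis
#'   vectors (`a1` = rows, `a2` = columns, with names).
#' @export
mip_project <- function(stack, axis = c("Z", "X", "Y")) {
  axis <- match.arg(axis)
  v <- stack$volume
  out <- switch(axis,
    Z = list(image = apply(v, c(2, 3), max), a1 = stack$x, a2 = stack$y,
             names = c("x_mm", "y_mm"), view = "TopView"),
    X = list(image = apply(v, c(1, 3), max), a1 = stack$z, a2 = stack$y,
             names = c("z_mm", "y_mm"), view = "SideView"),
    Y = list(image = apply(v, c(1, 2), max), a1 = stack$z, a2 = stack$x,
             names = c("z_mm", "x_mm"), view = "FrontView"))
  structure(c(out, list(axis = axis)), class = "mip_image")
}

#' Extract C-scan slices at chosen depths
#'
#' X-Y planes at the grid depths nearest each requested depth, or
#' thin-slab maxima over a stated thickness centered on each depth.
#'
#' @param stack A [stack_bscans()] volume.
#' @param depths Depths (same units as `stack$z`).
#' @param thickness Slab thickness (0 = single plane).
#' @return A `cscan_slices`: list of matrices `slices` (`[x, y]` each)
#'   with `depths`, axes `x`, `y`.
#' @export
extract_cscan_slices <- function(stack, depths, thickness = 0) {
  zr <- range(stack$z)
  if (any(depths < zr[1] - thickness / 2) || any(depths > zr[2] + thickness / 2)) {
    stop("requested depth outside the stack Z range", call. = FALSE)
  }
  slices <- lapply(depths, function(d) {
    sel <- if (thickness > 0) {
      which(stack$z >= d - thickness / 2 & stack$z <= d + thickness / 2)
    } else {
      which.min(abs(stack$z - d))
    }
    if (length(sel) == 0) sel <- which.min(abs(stack$z - d))
    apply(stack$volume[sel, , , drop = FALSE], c(2, 3), max)
  })
  structure(list(slices = slices, depths = depths,
                 x = stack$x, y = stack$y, thickness = thickness),
            class = "cscan_slices")
}

#' Depth-coded TopView projection
#'
#' Restricts the volume to a depth window, then for every X-Y position
#' records both the maximum intensity (brightness) and the depth at which
#' it occurs (color channel).  The brightness equals the windowed TopView
#' MIP by construction.
#'
#' @param stack A [stack_bscans()] volume.
#' @param z_window `c(min, max)` depth window (same units as `stack$z`).
#' @return A `depth_coded_image`: list with `intensity` and `depth`
#'   matrices (`[x, y]`), axes, and the window.
#' @export
depth_color_code <- function(stack, z_window) {
  sel <- which(stack$z >= z_window[1] & stack$z <= z_window[2])
  if (length(sel) == 0) stop("empty depth window", call. = FALSE)
  sub <- stack$volume[sel, , , drop = FALSE]
  zs <- stack$z[sel]
  intensity <- apply(sub, c(2, 3), max)
  depth <- apply(sub, c(2, 3), function(v) zs[which.max(v)])
  structure(list(intensity = intensity, depth = depth,
                 x = stack$x, y = stack$y, z_window = z_window),
            class = "depth_coded_image")
}

#' Overlay a thresholded PA image on a US image
#'
#' Renders the ultrasound image as the grayscale base and marks PA pixels
#' within `threshold_db` of the PA maximum for color overlay; pixels
#' below threshold keep the US value untouched.
#'
#' @param us_img,pa_img Numeric matrices of identical shape.
#' @param threshold_db Overlay threshold relative to the PA maximum
#'   (dB, default -20; 0 keeps only the maximum pixel, `-Inf` overlays
#'   everything).
#' @return An `overlay_image`: list with `us`, `pa`, logical
#'   `overlay_mask`, `threshold_db`.
#' @export
coregister_overlay <- function(us_img, pa_img, threshold_db = -20) {
  if (!all(dim(us_img) == dim(pa_img))) {
    stop("US and PA images must share geometry", call. = FALSE)
  }
  pmax_ <- max(pa_img)
  mask <- pa_img >= pmax_ * 10^(threshold_db / 20)
  structure(list(us = us_img, pa = pa_img, overlay_mask = mask,
                 threshold_db = threshold_db),
            class = "overlay_image")
}
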