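#' Absorbing primitive for digital phantoms
#'
#' A simple absorber: straight cylinder, sphere, or a curved tube whose
#' centerline is given as a parametric set of control points.
#'
#' @param shape `"cylinder"`, `"sphere"` or `"curved_tube"`.
#' @param center Center (mm, length 3) for sphere/cylinder.
#' @param axis Unit axis direction for cylinders (length 3).
#' @param length Cylinder length (mm, `Inf` = spans the grid).
#' @param diameter_um Diameter in micrometers (> 0).
#' @param mu_a_rel Relative absorption (>= 0, default 1).
#' @param path For curved tubes: a 3-column matrix of centerline control
#'   points (mm), interpolated with a natural spline.
#' @return An `absorber_primitive`.
#' @export
absorber_primitive <- function(shape = c("cylinder", "sphere", "curved_tube"),
                               center = c(0, 0, 10), axis = c(1, 0, 0),
                               length = Inf, diameter_um = 150,
                               mu_a_rel = 1, path = NULL) {
  shape <- match.arg(shape)
  if (diameter_um <= 0) stop("`diameter_um` must be > 0", call. = FALSE)
  if (mu_a_rel < 0) stop("`mu_a_rel` must be >= 0", call. = FALSE)
  if (shape == "curved_tube" && (is.null(path) || ncol(path) != 3)) {
    stop("curved_tube requires a 3-column `path`", call. = FALSE)
  }
  structure(list(shape = shape, center = center,
                 axis = axis / sqrt(sum(axis^2)), length = length,
                 diameter_um = diameter_um, mu_a_rel = mu_a_rel, path = path),
            class = "absorber_primitive")
}

#' Phantom specification
#'
#' @param primitives List of [absorber_primitive()] objects.
#' @param background An [optical_medium()] for the embedding medium.
#' @param grid A [cartesian_grid()] the phantom is defined on.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(primitives, background = lipofundin_1pct(),
                         grid = cartesian_grid(c(10, 10, 12), 0.1)) {
  structure(list(primitives = primitives, background = background,
                 grid = grid), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %d primitives in %s\n",
              length(x$primitives), x$background$name))
  invisible(x)
}

#' Two-hair lateral-resolution phantom
#'
#' Two parallel hairs of 150 um diameter at 10.2 mm depth with a 180-um
#' edge-to-edge gap (center separation 330 um), lying along x in a 1%
#' Lipofundin background: the standard bench test of whether the imaging
#' chain separates two sub-resolution targets.  The 180-um figure is read
#' as an edge-to-edge gap: a 180-um center distance between 150-um hairs
#' would make them overlap.
#'
#' @param gap_um Edge-to-edge gap (um, default 180).
#' @param diameter_um Hair diameter (um, default 150).
#' @param depth_mm Depth (mm, default 10.2).
#' @param gap_convention `"edge"` (default) or `"center"`.
#' @return A `phantom_spec` with two cylinders.
#' @export
make_two_hair_phantom <- function(gap_um = 180, diameter_um = 150,
                                  depth_mm = 10.2,
                                  gap_convention = c("edge", "center")) {
  gap_convention <- match.arg(gap_convention)
  sep_mm <- if (gap_convention == "edge") {
    (gap_um + diameter_um) / 1000
  } else {
    gap_um / 1000
  }
  hairs <- lapply(c(-1, 1), function(s) {
    absorber_primitive("cylinder",
                       center = c(0, s * sep_mm / 2, depth_mm),
                       axis = c(1, 0, 0), diameter_um = diameter_um,
                       mu_a_rel = 0.4)
  })
  # hairs separated along y here; the imaging x-axis maps onto whichever
  # lateral direction the array is aligned with when rasterized
  phantom_spec(hairs)
}

#' Multi-target depth-coded C-scan phantom
#'
#' One pencil lead (500 um), two black threads (~250 um) and one curved
#' black hair (~150 um), all within the 8.5-11 mm depth band, crossing a
#' 35-mm elevation scan: the standard multi-size object for depth-coded
#' reconstruction demos.  Relative absorptions (lead 1.0, thread 0.6,
#' hair 0.4) are display-oriented defaults.
#'
#' @return A `phantom_spec` with four primitives on a 35-mm-long grid.
#' @export
make_multi_target_phantom <- function() {
  grid <- cartesian_grid(c(16, 36, 16), 0.1)
  lead <- absorber_primitive("cylinder", center = c(-3, 0, 9.0),
                             axis = c(0, 1, 0), diameter_um = 500,
                             mu_a_rel = 1.0)
  thread1 <- absorber_primitive("cylinder", center = c(-1, 0, 9.7),
                                axis = c(0, 1, 0), diameter_um = 250,
                                mu_a_rel = 0.6)
  thread2 <- absorber_primitive("cylinder", center = c(1, 0, 10.4),
                                axis = c(0, 1, 0), diameter_um = 250,
                                mu_a_rel = 0.6)
  yy <- seq(-17, 17, length.out = 9)
  hair_path <- cbind(3 + 0.8 * sin(yy / 6), yy, 9.8 + 1.0 * cos(yy / 8))
  hair <- absorber_primitive("curved_tube", path = hair_path,
                             diameter_um = 150, mu_a_rel = 0.4)
  phantom_spec(list(lead = lead, thread1 = thread1, thread2 = thread2,
                    hair = hair), grid = grid)
}

#' Branching surface-vessel scene with optional occlusion
#'
#' A synthetic branching set of shallow tubes emulating cortical surface
#' vasculature for blood-volume change demos.  With `occluded = TRUE` one
#' branch's absorption is reduced by `occlusion_factor` and the
#' ground-truth change mask is returned with the spec.
#'
#' @param occluded Apply the occlusion (default `FALSE`).
#' @param occlusion_factor Fractional reduction of the occluded branch's
#'   absorption (default 0.8, i.e. the branch keeps 20%).
#' @return List with the `phantom_spec` and the logical `change_mask`
#'   over the grid's x-y plane.
#' @export
make_vessel_scene <- function(occluded = FALSE, occlusion_factor = 0.8) {
  grid <- cartesian_grid(c(10, 10, 4), 0.05)
  trunk <- absorber_primitive("cylinder", center = c(0, 0, 1),
                              axis = c(0, 1, 0), diameter_um = 400,
                              mu_a_rel = 1.0)
  b1 <- absorber_primitive("cylinder", center = c(-2, 2.5, 1),
                           axis = c(-0.6, 0.8, 0), length = 6,
                           diameter_um = 250, mu_a_rel = 1.0)
  b2 <- absorber_primitive("cylinder", center = c(2, -2.5, 1),
                           axis = c(0.6, 0.8, 0), length = 6,
                           diameter_um = 250,
                           mu_a_rel = if (occluded) 1 - occlusion_factor else 1)
  spec <- phantom_spec(list(trunk = trunk, branch_a = b1, branch_b = b2),
                       grid = grid)
  b2_only <- phantom_spec(list(b2), grid = grid)
  mask2d <- apply(rasterize_phantom(b2_only)$mu_a > 0, c(1, 2), any)
  list(spec = spec, change_mask = mask2d)
}

#' Synthetic oxygenation scene with known SO2
#'
#' A disc "tumor" of low oxygen saturation embedded in well-oxygenated
#' background tissue, with per-wavelength absorption maps built through
#' [absorption_from_concentrations()] so that two-wavelength unmixing has
#' an exact ground truth.
#'
#' @param n Image side (pixels, default 100).
#' @param so2_tumor Range of tumor SO2 (default `c(0.3, 0.6)`).
#' @param so2_background Range of background SO2 (default
#'   `c(0.9, 0.98)`).
#' @param hbt Total hemoglobin (mol/L relative units, default 1).
#' @param wavelengths The two acquisition wavelengths (nm).
#' @param seed RNG seed for the SO2 draws.
#' @param table An `extinction_table`.
#' @return List with `mu_a_l1`, `mu_a_l2`, `so2_true`, `hbt_true`,
#'   logical `tumor_mask`, and `wavelengths`.
#' @export
make_oxygenation_scene <- function(n = 100, so2_tumor = c(0.3, 0.6),
                                   so2_background = c(0.9, 0.98), hbt = 1,
                                   wavelengths = c(750, 850), seed = 1,
                                   table = read_extinction_table()) {
  set.seed(seed)
  xy <- expand.grid(i = seq_len(n), j = seq_len(n))
  r <- sqrt((xy$i - n / 2)^2 + (xy$j - n / 2)^2)
  tumor <- matrix(r <= n / 5, n, n)
  so2 <- matrix(stats::runif(n * n, so2_background[1], so2_background[2]), n, n)
  so2[tumor] <- stats::runif(sum(tumor), so2_tumor[1], so2_tumor[2])
  hbt_map <- matrix(hbt, n, n)
  hbo2 <- so2 * hbt_map
  hb <- (1 - so2) * hbt_map
  mu1 <- absorption_from_concentrations(wavelengths[1], hbo2, hb, table)
  mu2 <- absorption_from_concentrations(wavelengths[2], hbo2, hb, table)
  list(mu_a_l1 = mu1, mu_a_l2 = mu2, so2_true = so2, hbt_true = hbt_map,
       tumor_mask = tumor, wavelengths = wavelengths)
}

#' Rasterize a phantom to a voxel absorption map and scatterer list
#'
#' Voxelizes the primitives into a relative-absorption array on the
#' phantom grid (later-listed primitives overwrite earlier ones where
#' they overlap) and samples each primitive centerline into a point
#' scatterer list for the array-imaging forward model.
#'
#' @param spec A `phantom_spec`.
#' @param grid Override grid (default the spec's).
#' @param centerline_step Spacing of centerline scatterer samples (mm).
#' @return List with 3-D array `mu_a` (`[x, y, z]` on the grid) and a
#'   tibble `scatterers` (`x`, `y`, `z`, `reflectivity`).
#' @export
rasterize_phantom <- function(spec, grid = spec$grid, centerline_step = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  mu <- array(0, dim = grid$dim)
  pts <- list()
  h <- grid$spacing
  x0 <- grid$x[1]; y0 <- grid$y[1]; z0 <- grid$z[1]
  stamp_ball <- function(center, r_mm, value) {
    # mark all cells whose center lies within r of `center`
    ix <- which(abs(grid$x - center[1]) <= r_mm)
    iy <- which(abs(grid$y - center[2]) <= r_mm)
    iz <- which(abs(grid$z - center[3]) <= r_mm)
    if (!length(ix) || !length(iy) || !length(iz)) return(invisible())
    dx2 <- (grid$x[ix] - center[1])^2
    dy2 <- (grid$y[iy] - center[2])^2
    dz2 <- (grid$z[iz] - center[3])^2
    d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    box <- mu[ix, iy, iz, drop = FALSE]
    box[d2 <= r_mm^2] <- value
    mu[ix, iy, iz] <<- box
    invisible()
  }
  for (p in spec$primitives) {
    r_mm <- p$diameter_um / 2000
    step <- centerline_step %||% min(r_mm / 2, h / 2)
    if (p$shape == "sphere") {
      cl <- matrix(p$center, ncol = 3)
    } else if (p$shape == "cylinder") {
      if (is.finite(p$length)) {
        tt <- seq(-p$length / 2, p$length / 2, by = step)
      } else {
        span <- sqrt(sum(grid$extents^2))
        tt <- seq(-span / 2, span / 2, by = step)
      }
      cl <- cbind(p$center[1] + tt * p$axis[1],
                  p$center[2] + tt * p$axis[2],
                  p$center[3] + tt * p$axis[3])
    } else {
      npts <- max(200, nrow(p$path) * 40)
      s <- seq(0, 1, length.out = npts)
      u <- seq(0, 1, length.out = nrow(p$path))
      cl <- cbind(stats::spline(u, p$path[, 1], xout = s)$y,
                  stats::spline(u, p$path[, 2], xout = s)$y,
                  stats::spline(u, p$path[, 3], xout = s)$y)
    }
    keep <- cl[, 1] >= min(grid$x) - r_mm & cl[, 1] <= max(grid$x) + r_mm &
      cl[, 2] >= min(grid$y) - r_mm & cl[, 2] <= max(grid$y) + r_mm &
      cl[, 3] >= min(grid$z) - r_mm & cl[, 3] <= max(grid$z) + r_mm
    if (!any(keep)) stop("primitive lies outside the grid", call. = FALSE)
    cl <- cl[keep, , drop = FALSE]
    if (p$shape == "sphere") {
      stamp_ball(p$center, r_mm, p$mu_a_rel)
    } else {
      # union of balls along the centerline (sample spacing <= r/2)
      for (m in seq_len(nrow(cl))) stamp_ball(cl[m, ], r_mm, p$mu_a_rel)
    }
    pts[[length(pts) + 1]] <- tibble::tibble(
      x = cl[, 1], y = cl[, 2], z = cl[, 3], reflectivity = p$mu_a_rel)
  }
  list(mu_a = mu, scatterers = dplyr::bind_rows(pts))
}
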