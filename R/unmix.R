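#' Read a molar extinction coefficient table
#'
#' Whitespace-delimited text with three columns: wavelength (nm),
#' molar extinction of HbO2 and of Hb (cm^-1 per mol/L); `#` starts a
#' comment line.  Wavelengths must be strictly increasing and all
#' coefficients positive.
#'
#' @param path File path.  Defaults to the bundled table of
#'   representative literature values on a coarse NIR grid.
#' @return A tibble with columns `wavelength_nm`, `eps_hbo2`, `eps_hb`,
#'   class `extinction_table`.
#' @export
read_extinction_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "hb_extinction.tsv", package = "pasim")
  }
  raw <- utils::read.table(path, comment.char = "#",
                           col.names = c("wavelength_nm", "eps_hbo2", "eps_hb"))
  tab <- tibble::as_tibble(raw)
  if (any(diff(tab$wavelength_nm) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (any(tab$eps_hbo2 <= 0) || any(tab$eps_hb <= 0)) {
    stop("extinction coefficients must be > 0", call. = FALSE)
  }
  class(tab) <- c("extinction_table", class(tab))
  tab
}

# interpolated extinction pair at a wavelength (errors outside the range)
extinction_at <- function(table, wavelength) {
  rng <- range(table$wavelength_nm)
  if (any(wavelength < rng[1]) || any(wavelength > rng[2])) {
    stop(sprintf("wavelength outside table range [%g, %g] nm", rng[1], rng[2]),
         call. = FALSE)
  }
  c(eps_hbo2 = stats::approx(table$wavelength_nm, table$eps_hbo2, wavelength)$y,
    eps_hb = stats::approx(table$wavelength_nm, table$eps_hb, wavelength)$y)
}

#' Blood absorption coefficient from chromophore concentrations
#'
#' `mu_a(lambda) = eps_HbO2(lambda) [HbO2] + eps_Hb(lambda) [Hb]`, with
#' linear interpolation of the extinction table between tabulated
#' wavelengths.
#'
#' @param wavelength Wavelength (nm), inside the table range.
#' @param c_hbo2,c_hb Molar concentrations (mol/L); relative units are
#'   acceptable (the result is then relative too).
#' @param table An `extinction_table` (default bundled).
#' @return Absorption coefficient (1/cm), vectorized over concentrations.
#' @export
absorption_from_concentrations <- function(wavelength, c_hbo2, c_hb,
                                           table = read_extinction_table()) {
  eps <- extinction_at(table, wavelength)
  eps[["eps_hbo2"]] * c_hbo2 + eps[["eps_hb"]] * c_hb
}

#' Two-wavelength hemoglobin unmixing
#'
#' Treats the two co-registered pixel intensities as (relative)
#' absorption coefficients and solves the per-pixel 2x2 linear system
#' for `[HbO2]` and `[Hb]`; `HbT = [HbO2] + [Hb]` and
#' `SO2 = [HbO2] / HbT`.  Pixels with non-positive HbT, or with SO2
#' outside `[-mask_tol, 1 + mask_tol]`, are masked invalid; in-range SO2
#' is clipped to `[0, 1]`.
#'
#' @param img_l1,img_l2 Co-registered numeric matrices (or arrays of
#'   equal shape): intensities at `lambda1` and `lambda2`.
#' @param lambda1,lambda2 Wavelengths (nm), e.g. 750 and 850.
#' @param table An `extinction_table`.
#' @param mask_tol Tolerance band outside `[0, 1]` before an SO2 pixel is
#'   masked (default 0.05).
#' @return A `chromophore_map`: list of arrays `hbo2`, `hb`, `hbt`,
#'   `so2`, logical `mask` (TRUE = valid) plus the wavelength pair.
#' @export
unmix_two_wavelength <- function(img_l1, img_l2, lambda1, lambda2,
                                 table = read_extinction_table(),
                                 mask_tol = 0.05) {
  if (!all(dim(img_l1) == dim(img_l2))) {
    stop("images must be co-registered with identical shape", call. = FALSE)
  }
  e1 <- extinction_at(table, lambda1)
  e2 <- extinction_at(table, lambda2)
  E <- rbind(c(e1[["eps_hbo2"]], e1[["eps_hb"]]),
             c(e2[["eps_hbo2"]], e2[["eps_hb"]]))
  det_e <- E[1, 1] * E[2, 2] - E[1, 2] * E[2, 1]
  if (abs(det_e) < 1e-10 * max(abs(E))^2) {
    stop("extinction matrix is singular at this wavelength pair",
         call. = FALSE)
  }
  Einv <- matrix(c(E[2, 2], -E[2, 1], -E[1, 2], E[1, 1]), 2, 2) / det_e
  hbo2 <- Einv[1, 1] * img_l1 + Einv[1, 2] * img_l2
  hb <- Einv[2, 1] * img_l1 + Einv[2, 2] * img_l2
  hbt <- hbo2 + hb
  so2 <- ifelse(hbt > 0, hbo2 / hbt, NA_real_)
  mask <- hbt > 0 & !is.na(so2) & so2 >= -mask_tol & so2 <= 1 + mask_tol
  so2 <- pmin(pmax(so2, 0), 1)
  structure(list(hbo2 = hbo2, hb = hb, hbt = hbt, so2 = so2, mask = mask,
                 lambda = c(lambda1, lambda2)),
            class = "chromophore_map")
}

#' @export
print.chromophore_map <- function(x, ...) {
  cat(sprintf("<chromophore_map %g/%g nm> %s px, %.1f%% valid, median SO2 %.3f\n",
              x$lambda[1], x$lambda[2], paste(dim(x$hbt), collapse = " x "),
              100 * mean(x$mask), stats::median(x$so2[x$mask])))
  invisible(x)
}

#' Relative cerebral-blood-volume proxy from an isosbestic image
#'
#' At a wavelength close to the hemoglobin isosbestic point (~800 nm)
#' the PA intensity is proportional to total hemoglobin regardless of
#' oxygenation, so a single-wavelength image normalized to a reference
#' region mean serves as a relative blood-volume map.
#'
#' @param img_800nm Numeric matrix of intensities at the isosbestic
#'   wavelength.
#' @param reference Logical matrix selecting the normalization region
#'   (default: all finite pixels).
#' @param reference_mean Optional fixed normalization value (e.g. the
#'   reference-region mean of a baseline acquisition) so that serial
#'   maps share one scale and intensity changes carry through.
#' @return Matrix of relative CBV values (reference mean = 1).
#' @export
cbv_proxy <- function(img_800nm, reference = NULL, reference_mean = NULL) {
  if (is.null(reference_mean)) {
    if (is.null(reference)) reference <- is.finite(img_800nm)
    if (!any(reference)) stop("empty reference region", call. = FALSE)
    reference_mean <- mean(img_800nm[reference])
  }
  if (reference_mean == 0) {
    stop("reference region has zero mean", call. = FALSE)
  }
  img_800nm / reference_mean
}

#' Inter-wavelength incident-intensity balancing factor
#'
#' Solves the illumination problem in the medium as seen at each of two
#' wavelengths and returns the multiplier to apply to the incident energy
#' at the first wavelength so both deliver the same fluence at the stated
#' depth: `factor = fluence(lambda2) / fluence(lambda1)` at the midline
#' observation point.
#'
#' @param medium_l1,medium_l2 [optical_medium()] objects for the two
#'   wavelengths.
#' @param depth Matching depth (mm, default 10).
#' @param geom,pulse,grid Illumination configuration (defaults as in
#'   [solve_fluence()]).
#' @return A single positive scale factor.
#' @export
wavelength_intensity_balance <- function(medium_l1, medium_l2, depth = 10,
                                         geom = illumination_geometry(),
                                         pulse = pulse_profile(),
                                         grid = cartesian_grid()) {
  f1 <- fluence_at_depth(solve_fluence(medium_l1, pulse, geom, grid), depth)
  f2 <- fluence_at_depth(solve_fluence(medium_l2, pulse, geom, grid), depth)
  f2 / f1
}
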