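Package: pasim
Title: Photoacoustic Imaging System Design Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Forward-simulation and reconstruction toolkit for designing
    dual-arm fiber-illuminated, linear-array photoacoustic (PA) imaging
    systems.  Solves pulsed-light diffusion in scattering media with Robin
    boundary conditions for a two-arm illumination geometry, models
    thermoelastic PA wave generation at a micro-scale spherical absorber,
    simulates linear-array point-scatterer responses with delay-and-sum
    beamforming and point-spread-function characterization, performs
    two-wavelength hemoglobin spectral unmixing (HbT and oxygen
    saturation), and assembles B-scan stacks into maximum-intensity
    projections, C-scan slices and depth-coded composites.  Digital
    phantoms reproduce standard resolution and oxygenation test objects so
    the whole chain runs without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    yaml,
    tiff,
    generics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    patchwork
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
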