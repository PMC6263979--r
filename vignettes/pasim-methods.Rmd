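---
title: "Models and numerical methods behind pasim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods behind pasim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pasim)
```

`pasim` simulates the design chain of a dual-arm, fiber-illuminated,
linear-array photoacoustic (PA) imaging system: pulsed-light transport in a
scattering medium, thermoelastic wave generation at a micro-scale absorber,
linear-array point-scatterer imaging with delay-and-sum (DAS)
reconstruction, two-wavelength hemoglobin unmixing, and volume
reconstruction from B-scan stacks.  This vignette documents the models, the
parameters that matter, the numerical choices, and the places where the
design was genuinely open and the package had to commit to a convention.

## Light transport

Light propagation in a highly scattering medium (the bench standard is a 1%
Lipofundin emulsion, $\mu_a = 0.026\,\mathrm{cm^{-1}}$,
$\mu_s' = 6.31\,\mathrm{cm^{-1}}$, $n = 1.35$ near 785 nm) is modelled with
the diffusion approximation

$$\frac{n}{c}\frac{\partial \varphi}{\partial t}
  + \nabla\cdot(-D\nabla\varphi) + \mu_a \varphi = P_0,
  \qquad D = \frac{1}{3(\mu_s' + \mu_a)},$$

with a temporally Gaussian source of pulse energy $W_p$ (default 20 mJ),
width $\tau_p$ (5 ns) and peak time 30 ns.  All outer faces carry the Robin
condition $-D\nabla\varphi\cdot\hat n = h\varphi$ with
$h = \tfrac12(1-R_\mathrm{eff})/(1+R_\mathrm{eff})$ and the Egan–Hilgeman
curve fit for the internal reflection $R_\mathrm{eff}(n)$; at $n=1.35$,
$h \approx 0.171$.

**Source placement.**  Collimated light entering the surface propagates
ballistically over one transport mean free path
$Z_0 = 1/(\mu_a+\mu_s')$ ($\approx 1.58$ mm here) before the diffusive
description applies, so each fiber arm is represented as a buried
rectangular source patch.  The patch dimensions are the fiber output
(16.5 × 0.8 mm) grown by the NA cone, $\Delta = Z_0\tan(\arcsin(NA/n))$ —
one total increment per dimension, which reproduces the standard
16.76 × 1.06 mm footprint for NA 0.22.  Three conventions were open for how
an arm tilted by $\alpha$ places its patch:

* depth: the ballistic segment has length $Z_0$ *along the ray*, so the
  patch sits at depth $Z_0\cos\alpha$ (not $Z_0$);
* lateral: the package keeps the patch centers at $\pm\,\mathrm{interval}/2$
  (`tilt_shift = "none"`, with `"inward"`/`"outward"` selectable).  The
  inward reading ($Z_0\sin\alpha$ toward the midline) reverses the expected
  ordering of midline fluence with incident angle — at 85° the centers move
  so much closer to the midline that the shallow-depth fluence *exceeds*
  the 15° case — so it cannot be the geometry behind the published design
  sweeps this package emulates;
* intensity: total energy is conserved through the ballistic segment
  (scaled only by the 5% surface reflection).  A $\cos\alpha$ energy
  scaling would impose a ~91% loss at 85°, an order of magnitude more than
  the few-tens-of-percent angle effects such sweeps report.

The patch is deposited one cell thick with mass-conserving linear
interpolation between the two bracketing grid layers; without that
interpolation the solution does not converge cleanly under grid refinement
because the 85° patch depth (0.14 mm) is a fraction of a cell.

**Discretization.**  Cell-centered finite differences with the 7-point
Laplacian on a regular grid (default domain 160 × 80 × 50 mm).  The Robin
condition is imposed by eliminating the face value, which adds
$\alpha/h$ with $\alpha = 2Dh_b/(h_b\,h+2D)$ to the diagonal of boundary
cells and keeps the operator symmetric positive definite.  The steady
(time-integrated) problem — the default for design sweeps, since relative
fluence at fixed positions is identical for the time-integrated field — is
solved matrix-free by conjugate gradients in C++ (relative tolerance
$10^{-8}$); the discrete energy balance (absorption + boundary loss =
injected energy) then holds to well under 1%.  The transient mode uses
Crank–Nicolson steps ($\Delta t = \tau_p/20$) on an assembled sparse
operator; it is intended for small grids, and its time integral reproduces
the steady field exactly, which the test suite asserts to 1%.  The
diffusion time to centimetre depths in this medium is sub-nanosecond, so
the 5-ns pulse is quasi-static and the steady mode loses no information.

Design sweeps run at 0.5 mm spacing (5.1 M cells, ~20 s per solve on one
core); module tests use 1–2 mm grids.  The 35° midline fluence at 10 mm
depth changes by under 2% when the spacing is halved; quantities involving
the 85° arm are more grid-sensitive (its source sits a fraction of a cell
below the surface), which is why the angle-sweep checks run at the
production 0.5 mm spacing.

**What matches and what does not.**  With these conventions the package
reproduces the canonical orderings (fluence decreasing with incident angle
and with arm interval, differences shrinking with depth) and the printed
shallow-depth angle deficit (~24% at 3 mm).  It does *not* reproduce two
published interval numbers (18.8% for 30- vs 10-mm interval at 10 mm depth;
3.35× PA signal for 14- vs 22-mm interval): a diffusion solve of the stated
geometry gives ~27% and ~1.7×.  An independent dipole (image-source)
estimate of the same geometry agrees with the solver, and no smooth decay
law can satisfy both printed numbers simultaneously (0.188 over a 20-mm
interval change implies ~1.95× over 8 mm, not 3.35×), so the package
reports what the stated physics yields rather than calibrating toward
either figure.

## Photoacoustic generation at a micro-target

The micro-scale chain couples, in spherical symmetry around a graphite
sphere (radius 6 µm) inside a 300-µm medium sphere:

1. **Heating**: $\rho C\,\partial T/\partial t = \nabla\cdot(k\nabla T) + Q$
   with $Q = \varphi\mu_a Y$ (heat yield $Y = 1$ by default) applied
   uniformly inside the optically small target.  The density factor
   belongs on the storage term on dimensional grounds and is included.
   Finite-volume discretization (0.1 µm cells), harmonic-mean face
   conductivities across the material interface, implicit Euler steps
   ($\tau_p/20$) with a reused sparse factorization, fixed temperature at
   the outer boundary.
2. **Thermal strain**: $\varepsilon = \beta(T - T_\mathrm{ref})$, positive
   on heating (the expansion sign convention).  The quasi-static map
   $u(t) = R_\mathrm{target}\,\varepsilon(t)$ of the volume-averaged target
   temperature gives the radial surface displacement; Young's modulus and
   the Poisson ratio are carried in the material type but unused on this
   default path (a full modal solid-mechanics treatment would need them).
3. **Radiation**: $u''(t)$ (central differences on a lightly smoothed
   $u(t)$, Gaussian width one step) drives
   $\hat n\cdot(\nabla p/\rho) = -u''$ at the target surface, and the
   pressure obeys the lossless wave equation outside the target.  The
   substitution $q = rp$ reduces spherical symmetry to the 1-D plane wave
   equation, integrated by leapfrog at CFL 0.5, with the outgoing
   characteristic at the outer edge (exact in $q$, equivalent to
   $p_t + c_sp_r + c_sp/r = 0$).  The pressure *inside* the target is not
   modelled.  A 2-D X–Z slice solver renders qualitative wavefield
   snapshots.

The tests verify $1/r$ peak decay to 5%, front propagation at $c_s$ to 5%,
strict linearity of the chain in pulse energy (1%), causality, and that the
radiated acoustic energy stays below the deposited thermal energy.
Graphite/Lipofundin thermal and elastic constants are shipped as documented
defaults (`graphite_material()`, `lipofundin_material()`); because such
constants are rarely printed alongside published design studies, every
shipped check that crosses this module is ratio-based so they cancel.

## Linear-array imaging

The array model is a 128-element, 0.10-mm-pitch receiver centered at
18.5 MHz with a 67% two-sided −6 dB fractional bandwidth, sampled at
62.5 MHz, sound speed 1540 m/s.  The pulse is a Gaussian-enveloped
sinusoid whose −6 dB spectral width equals the stated fractional bandwidth
($\sigma_t = 0.3741/\Delta f$, verified by FFT in the tests).  Point
scatterer RF uses plane-wave (flash) transmit for pulse-echo, hard-baffle
element directivity $\mathrm{sinc}(\pi w \sin\theta/\lambda)$ with element
width $0.9\times$ pitch (kerf unstated in typical array specs), and
spherical spreading.  DAS beamforming interpolates the analytic signal at
the round-trip (or one-way) delay with a dynamic receive aperture at
f-number 1.0 and Hann apodization (both configurable; `f_number = 0`
removes the aperture limit); the envelope is the magnitude of the complex
sum, and log compression is display-only.

Two consequences of this model are worth stating because they bound what a
bandwidth-faithful simulation can reproduce of vendor-reconstructed
figures:

* the two-way envelope of a 67% band at 18.5 MHz is ~100 ns long, so the
  axial FWHM is ~77–80 µm.  A printed axial resolution of ~167 µm implies
  an effective ~4-cycle pulse (~22% bandwidth); both cannot hold at once,
  and the package follows the stated bandwidth;
* a dynamic aperture at fixed f-number makes lateral resolution
  depth-invariant by construction, so the depth-degradation visible in
  fixed-aperture reconstructions only appears here toward the depths where
  the 12.8-mm physical aperture saturates, or with `f_number = 0`.

The two-point study places equal scatterers at a lateral separation,
extracts the lateral envelope profile through the peak, and classifies the
pair resolvable when the profile shows two local maxima whose valley is at
least 3 dB below the lower peak.  Only maxima above −20 dB of the profile
peak enter the census: two fully coherent in-phase points closer than the
PSF width produce faint interference ripples that would otherwise register
as spurious peak pairs.  Both thresholds are arguments
(`dip_db`, and the floor inside the classifier); a near-0 dB dip
criterion reproduces more generous "distinguishable by eye on a log-scale
display" readings, and with the 3 dB criterion the package reports minimum
resolvable separations of roughly 1.2× the local lateral FWHM.

## Spectral unmixing and reconstruction

Two co-registered images at wavelengths $\lambda_1,\lambda_2$ (750/850 nm
by default) are treated pixel-wise as relative absorption coefficients and
inverted through the 2 × 2 molar-extinction system to
$[\mathrm{HbO_2}]$ and $[\mathrm{Hb}]$; $\mathrm{HbT}$ is their sum and
$\mathrm{SO_2} = [\mathrm{HbO_2}]/\mathrm{HbT}$.  No fluence-depth
compensation is applied inside the image by default (published maps of
this kind are normalized); `wavelength_intensity_balance()` provides the
complementary knob, the incident-energy multiplier that equalizes
delivered fluence at a stated depth between the two wavelengths'
optical-property sets.  Pixels with non-positive HbT or SO₂ outside
$[-0.05, 1.05]$ are masked (band configurable), in-range values clipped to
$[0,1]$.  A bundled plain-text table carries representative literature
molar extinction values on a coarse 600–1000 nm grid; every accuracy
claim in the tests is a synthetic round-trip through the same table, so
the table's provenance cannot affect correctness checks.  An
800-nm image (the hemoglobin isosbestic region) normalized to a reference
mean serves as the relative blood-volume proxy.

Reconstruction operates on stacks of X–Z envelope B-scans with a uniform
elevation step (default 50 µm): maximum intensity projections along any
axis ("column" = the projection line; the TopView projects along depth),
C-scan planes or thin-slab maxima, a depth-coded TopView whose hue encodes
the depth of the per-pixel maximum (HSV ramp over the window; the
brightness channel equals the windowed MIP by construction), and
US/PA overlays thresholded in dB relative to the PA maximum (default
−20 dB).  All of these are exact array reductions and are tested against
brute-force oracles.

## Phantoms

Digital phantoms make the whole chain testable without an instrument:

* `make_two_hair_phantom()`: two 150-µm cylinders at 10.2 mm depth with a
  180-µm gap.  The gap is read edge-to-edge (center separation 330 µm): a
  180-µm *center* separation of 150-µm hairs would overlap them.  The
  convention is switchable.
* `make_multi_target_phantom()`: a 500-µm pencil lead, two ~250-µm
  threads and a curved ~150-µm hair, all inside the 8.5–11 mm depth band,
  crossing a 35-mm elevation scan.  The relative absorptions (1.0, 0.6,
  0.4) are display-oriented defaults; nothing quantitative depends on
  them.
* `make_vessel_scene()`: a branching shallow-tube set with an optional
  80% absorption reduction of one branch and its ground-truth change
  mask, for blood-volume change demos.
* `make_oxygenation_scene()`: a low-SO₂ disc (0.3–0.6) in well-oxygenated
  background (0.9–0.98) whose per-wavelength absorption maps are built
  through the same extinction table the unmixer uses, giving an exact
  round-trip ground truth; with 5% multiplicative noise the median SO₂
  error stays below 0.05.

Rasterization stamps union-of-balls along densely sampled centerlines
(sample spacing at most half the tube radius), which converges to analytic
volumes as the grid refines (the sphere check runs at two spacings) and is
bit-deterministic.

## File formats and the pipeline

Volumes and images travel as multi-page 32-bit TIFF with a YAML sidecar
for amplitude scale and axes (the codec quantizes to a $2^{32}$ grid —
about one part in $10^{9}$ — and the reader compensates the codec's
asymmetric encode/decode scales so grid-representable values round-trip
bit-exactly); tables as CSV; configurations and run manifests as YAML.
`load_config()` fills the standard design-study defaults and rejects
unknown keys by name; `run_pipeline()` threads stages (fluence → PA;
phantom → reconstruction), seeds all randomness from the single config
seed, and writes an atomically renamed manifest with the configuration
hash and output inventory.  `inst/scripts/pasim` is a thin command-line
wrapper over these two functions.

## Known limitations

* Homogeneous media only; no layered tissue, no wavelength-dependent
  property libraries beyond per-run scalars, no Monte Carlo transport.
* The acoustic path ignores frequency-dependent attenuation and
  nonlinearity; the solid mechanics of the target is quasi-static.
* Imaging simulation is ray-based DAS, not full-wave; no elevation focus,
  no speckle from diffuse scatterer fields.
* Phantom tests exercise ideal point/cylinder targets in noise-free or
  synthetically noised conditions; passing them bounds algorithmic
  correctness, not in-vivo image quality.
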