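---
title: "A virtual DHM dry-mass cytotoxicity assay: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A virtual DHM dry-mass cytotoxicity assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holomass)
```

## The assay in one paragraph

Quantitative phase imaging (QPI) with off-axis digital holographic
microscopy (DHM) measures the optical path-length shift a transparent
cell imposes on transmitted light.  Because that shift integrates the
intracellular solute content, the **population dry mass** inside a fixed
field of view (FOV) can be computed from the mean phase shift
$\bar{\Delta\varphi}$:

$$ dm = \frac{\lambda}{2\pi\alpha}\,\bar{\Delta\varphi}\,S_{FOV}, $$

with laser wavelength $\lambda$ (532 nm), the specific refractive
increment of cellular protein $\alpha$ (0.19 mL/g), and the FOV area
$S_{FOV}$ (450 µm × 338 µm = 152,100 µm²).  Tracking $dm$ every 30 min
for 24 h and taking the increment $dm(24\,\mathrm{h}) - dm(0)$ per FOV
turns label-free imaging into a cytotoxicity endpoint: healthy
populations gain mass, arrested ones stay flat, and lysing ones lose
mass (a negative increment).  Endpoints from $n = 4$ positions per well
across $N = 3$ independent experiments are compared by a two-sided
Student's *t*-test with Bonferroni correction.

`holomass` implements this assay as a closed loop that can be audited
end to end: a phantom generator with *closed-form* ground-truth mass, a
physically explicit hologram forward model, the full reconstruction
chain, rolling-ball background correction, and the endpoint statistics.

## The phase and mass models

A phantom cell is a rotationally symmetric thickness profile $d(x,y)$
(truncated paraboloid by default) with an integral refractive index
$n_{cell}$ in medium $n_{medium}$; its phase footprint is

$$ \Delta\varphi(x,y) = \frac{2\pi}{\lambda}\, d(x,y)\,
   (n_{cell} - n_{medium}). $$

Because the profile volumes have closed forms ($\pi R^2 d/2$ for the
paraboloid), the scene's dry mass
$\sum_k (n_{cell,k}-n_{medium})V_k/\alpha$ is exact, independent of any
raster.  This is the yardstick every pipeline result is measured
against; the wavelength cancels in it by construction.

**Defaults (the package's stated world).**  The source experiments do
not publish per-cell phase values, sizes or refractive indices, so these
are free simulation parameters chosen once:

| parameter | default | why |
|---|---|---|
| grid | 512 × 384 px @ 0.879 µm/px | matches the printed 450 µm × 338 µm FOV at desk scale |
| $n_{medium}$ | 1.337 | culture medium |
| $n_{cell}$ | U(1.372, 1.387) | typical integral cell indices |
| footprint radius | U(10, 15) µm | spread adherent cells, 20–30 µm across |
| thickness | U(5, 8) µm | rounded (macrophage-like) morphology |
| cells per FOV | 70 | ≈ 25 ng initial population mass, matching the reported control scale |

Tests that require wrap-free phase (< π) use a flattened morphology
(thickness 1.5–2.5 µm), which is equally realistic for well-spread
cells.

**Temporal scenarios.**  Five laws reproduce the qualitative course
types seen in 24-h time-lapse data: exponential growth
($m_0 2^{t/T_d}$, $T_d$ = 24 h so the 24-h increment equals $m_0$ ≈ 25
ng), linear growth (0.2 ng/h, the few-ng range of slower lines), arrest,
lysis ($m_0 e^{-k(t-t_0)}$ with $k$ = 0.0165/h, $t_0$ = 1 h, giving a
−7.9 ng increment from 25 ng — the magnitude reported for the lysed
condition), and delayed toxicity (growth to a 10-h onset, then decline).
`evolve()` scales cell thicknesses so the scene's analytic mass meets
the law *exactly*; under lysis the visible mass is cells plus debris,
where debris carries 30% of the cellular loss (the rest dissolves).
Debris is rendered as many ~15 pg paraboloid fragments (3–6 µm) rather
than few large ones: gentle fragments keep both the raster and the
band-limited reconstruction faithful.

## The hologram forward model

The object wave $O = A_o e^{i\varphi}$ is optionally multiplied by a
quadratic aberration phase $e^{iar^2}$ (the spherical aberration of
objective and tunable lens, $r$ in pixels about the grid centre),
propagated by a defocus distance, and interfered with a tilted plane
reference $R = A_r e^{-2\pi i(f_x x + f_y y)}$:

$$ I = |O e^{i\eta} + R|^2 , $$

with carrier $f$ = (0.25, 0.25) cycles/px by default — far from DC,
below Nyquist, off the spectral axes.  $\eta$ is a smooth random phase
screen (low-pass-filtered white noise, correlation length 8 px), redrawn
per frame: this emulates the frame-to-frame decorrelation produced by
modulating the illumination, which is what 15-frame averaging is
designed to suppress.  The noise *law* is our assumption; the source
only states that averaging reduces coherence-induced disturbances.
Detector noise is additive Gaussian; intensity is clipped at zero.  The
sign convention makes the order carrying $+\varphi$ land at $+f$ in the
canonical half-plane, so cells reconstruct with positive phase.

## Reconstruction chain and its numerical choices

Per frame: FFT → sideband isolation → re-centering → inverse FFT →
atan2 phase → aberration compensation → optional refocusing → unwrap;
the unwrapped maps of one timepoint are then averaged (phase-domain
averaging, as stated; complex averaging is available but non-default).

* **Sideband location.**  Magnitude maximum outside a DC exclusion zone
  (0.05 cyc/px), searched in the canonical half-plane.  The support
  radius is where the radially averaged magnitude falls to 1% of the
  peak, capped at half the carrier distance.  The carrier itself is then
  refined to the magnitude² *centroid* of the support region: under
  strong aberration the sideband is a broad chirp disc whose maximum bin
  wanders, while its centroid stays on the carrier — re-centering on the
  raw maximum would inject a tilt of up to the disc radius.
* **Mask.**  Hard disc of radius 0.4 × carrier distance (raised-cosine
  edge available).  A mask that reaches into the DC exclusion zone is a
  configuration error with a diagnostic.  Integer-bin carriers (the
  default on the default grid) make tilt removal exact; sub-bin carriers
  leave ≤ one fringe of residual tilt, by construction of an
  integer-bin spectrum shift.
* **Aberration compensation.**  A quadratic phase $ar^2$ broadens the
  sideband to roughly $aN/2\pi$ cycles/px, so the support radius gives a
  coarse $a_0 = 2\pi r_{supp}/N$.  Because one spectral bin corresponds
  to a large curvature quantum, $a_0$ is refined by maximizing the
  spectral concentration (peak magnitude) of
  $U e^{-i\hat{a}r^2}$ over a bracket around $a_0$ — a standard focus
  metric.  The correction is applied only when it sharpens the spectrum
  by more than 10% over $\hat a = 0$: object bandwidth alone also
  broadens the sideband, and without the gate an aberration-free phantom
  would receive a spurious correction.  This whole estimator is our
  documented model choice; the source states the principle (curvature
  from the sideband size) but not the functional form.
* **Refocusing.**  Angular-spectrum transfer function
  $\exp(2\pi i z\sqrt{\lambda^{-2} - f^2})$; evanescent frequencies are
  zeroed.  The operator is unitary on band-limited fields and exactly
  invertible ($z$ then $-z$).
* **Unwrapping.**  Reliability-sorted region-growing unwrapping (edge
  quality from wrapped second differences, union-find merging), robust
  to closed wrap contours on cell images.  The result is congruent to
  the input modulo 2π pixelwise and normalized by a global 2πk so the
  background mode sits near zero.
* **Averaging before background correction**, with no per-frame piston
  alignment: with a fixed integer-bin carrier the extraction piston is
  stable frame to frame, so alignment would only hide real drift.

## Rolling-ball background correction

The irregular, slowly varying phase background (well-bottom thickness
variations) is estimated as the grayscale opening of the image by a
spherical-cap structuring element — the surface a ball of radius 50 px
(~44 µm, several cell radii) traces when rolled under the phase
surface — and subtracted.  The ball's *aspect* (0.005 rad of cap height
per pixel) sets its curvature to 10⁻⁴ rad/px²: flatter than any
plausible well-bottom curvature (so real background is followed
exactly) yet steep enough that the intrusion under a 25 px cell stays
below 1% of the cell phase.

Two measures control the known bias of morphological background
estimators under noise, both with precedents in the standard ImageJ
implementation this stage mirrors: the background is estimated on a
lightly smoothed copy (5 × 5 mean; the subtraction itself uses the
original image), and the corrected map is re-zeroed on its phase mode —
the package's piston convention is that the specimen-free level defines
zero, and the mode is the specimen-free level whenever cells cover less
than about half the FOV.  Without these, the opening rides the minima of
the residual reconstruction ripple and inflates population mass by
5–10%.  The pure opening (`smooth_px = 1`, `zero_mode = FALSE`) remains
available and is what the package's erosion–dilation oracle and
monotonicity/idempotence contracts test.

## Endpoint statistics

Per-FOV increments $dm(24) - dm(0)$ are compared by a two-sided pooled
two-sample *t*-test (`var.equal = TRUE`, the plain Student test named by
the protocol), Bonferroni-adjusted over the number of simultaneous
treated-vs-control comparisons, and labelled `***`/`**`/`*`/`ns` at
adjusted p < 0.005 / 0.01 / 0.05.  Degenerate zero-variance groups
define p = 1 (equal means) or 0.  An optional variance-homogeneity
F-test can be enabled as a pre-test; it only warns and never changes the
reported test, since the protocol does not specify what its pre-test
was.

## Simulation fidelity modes and what a green test establishes

`run_virtual_experiment()` offers three fidelity modes:

* `"full"` — hologram stacks, reconstruction, background correction per
  timepoint.  Used to establish that the imaging chain recovers analytic
  phantom mass within 2% (noise-free) / 5% (default noise, 15 frames).
* `"phantom"` — rendered phase quantified directly (no holography).
* `"series"` — dry-mass series drawn from the scenario law plus noise:
  FOV initial mass ~ N(25, 2²) ng, per-timepoint measurement noise 0.5
  ng.  This is the mode for replicate-heavy statistical studies (100
  replicates of an N = 3 × n = 4, 49-timepoint, two-arm experiment run
  in seconds; the full chain would need ~10⁵ reconstructions).

The generator emulates: carrier fringes, quadratic aberration, defocus,
per-frame decorrelated coherent noise, detector noise, growth/arrest/
lysis/delayed-toxicity dynamics, debris.  It does **not** emulate cell
motility, division events, shot-noise statistics, vibration, or focus
drift — so a green suite establishes the correctness of the *method
chain*, not performance on any specific instrument.  Absolute phantom
optics are plausible but uncalibrated against any particular cell line
(the source publishes none).

## Worked example

```{r example, eval = FALSE}
library(holomass)

cfg <- experiment_config(
  conditions = list(
    condition_arm("medium control",
                  scenario_spec("control-exponential"), control = TRUE),
    condition_arm("empty PACA 32", scenario_spec("lysis"), 32)),
  seed = 1, outdir = "run1")
res <- run_virtual_experiment(cfg)
res$stats
#>        condition concentration_ug_per_ml  n   mean_ng    sd_ng         t
#> 1 medium control                       0 12 25.012012 1.715762        NA
#> 2  empty PACA 32                      32 12 -8.200926 1.020210 -57.63707
#>              p        p_adj stars
#> 1           NA           NA  <NA>
#> 2 1.685712e-25 1.685712e-25   ***
```

The control arm gains ~25 ng per FOV over 24 h; the lysing arm loses
~8 ng; the Bonferroni-adjusted p-value earns `***` under the printed
convention.

## Known limitations

* The aberration estimator assumes a purely quadratic (defocus-like)
  term; higher Zernike orders are out of scope.
* The mode-based re-zeroing of corrected maps assumes a mostly
  specimen-free background; near-confluent fields should disable
  `zero_mode` and accept the small documented bias.
* The sign of reconstructed phase follows the package's carrier
  convention; data recorded with the opposite reference tilt
  reconstructs with inverted phase.
* TIFF support covers the uncompressed little-endian float/uint subset
  the pipeline writes, not arbitrary vendor TIFFs.
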