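---
title: "Methods: the stormtrace analysis chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the stormtrace analysis chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, algorithms, parameter choices and known
limitations of the package, stage by stage. It states no empirical result
that the test suite does not itself compute.

## The problem

Single-molecule localization microscopy (STORM) reconstructs an image from
many sparse activation/localization cycles of photoswitchable fluorophores.
For tracing thin neural processes the decisive quantities are:

* **localization precision** — the FWHM of the scatter of repeated position
  estimates of one emitter, set by photon statistics;
* **label density** *a* — labels per µm² (2D) or µm³ (3D) of structure.

By the Nyquist sampling criterion the density alone limits resolution to
twice the mean neighbor spacing, `alpha = 2 / a^(1/d)` (nm when *a* is per
µm^d, handled by `nyquist_resolution()`), and since precision and sampling
are independent error sources the final resolution adds them in quadrature
(`combined_resolution()`). At `a = 2500` labels/µm², `d = 2` and 18 nm
precision this yields `sqrt(40^2 + 18^2) = 43.9 ≈ 44` nm. The divisor
`n` (default 4) converts localization density to label density, because each
fluorophore yields several switching events; the densities the package
reports are post-division label densities.

## Synthetic data generator

`make_structure()` places labels by a homogeneous Poisson point process on
the *membrane surface* of tubes (neurite stand-ins), X/Y junctions (two tubes
crossing with a configurable axial separation) or flat patches. Membrane
placement matters: a 75 nm-radius tube imaged in cross-section shows two
membrane peaks ~150 nm apart, and surface labeling is what makes thin
processes well-sampled.

`schedule_blinking()` implements the interleaved activation/imaging cycle.
The default single-color cycle is one activation frame followed by three
imaging frames; the multicolor cycle is two activation + three imaging frames
per activator (405/457/532 nm). A label activated by its own pulse appears in
the first imaging frame after that pulse; nonspecific (imaging-laser)
activations are uniform over imaging frames; wrong-laser activations follow
another channel's pulse. Each label contributes
`mean_localizations_per_label` events on average (default 4, matching the
divisor of the density calculus); all events of a label share its true
position, so localization scatter comes only from photon-limited fitting.
Cycles are integer frame patterns; fractional-frame activation timing is not
modeled, and the per-cycle activation probability is the free parameter that
sets how fast labels are consumed.

`render_frames()` is the forward model: each event adds a pixel-integrated
elliptical Gaussian with widths taken from the same calibration curve the
analysis uses (forward and inverse models must match for round-trip tests),
truncated at the detectable z-range (the calibration's valid range, ±400 nm
by default). The camera model is Poisson shot noise + Gaussian read noise +
constant offset; EM-gain excess noise is deliberately omitted (it rescales
the effective photon count without changing any algorithmic behavior under
test). Photon yields per event are Gamma-distributed (shape 4) around
`photons_mean` (default 5000, typical of a bright cyanine reporter; a free
simulator parameter).

What the simulator does **not** emulate: dark-state kinetics and bleaching,
aberrations beyond astigmatism, background structures, sCMOS-style pixel
noise. Passing tests therefore validate the analysis chain's correctness and
internal consistency, not robustness to every feature of real data.

## Calibration

Astigmatic 3D encodes z in the x/y width asymmetry introduced by a
cylindrical lens. `build_calibration()` fits the standard defocusing
polynomial per axis,

`w(z) = w0 * sqrt(1 + u^2 + A u^3 + B u^4)`, `u = (z - c)/d`,

with a smoothing-spline alternative (`method = "spline"`). Invertibility is
enforced: the signed difference `wx - wy` must be strictly monotonic over the
sampled range, otherwise an "uninvertible calibration" error is raised
(e.g. no astigmatism). The valid range is the sampled z interval;
`widths_at()` refuses extrapolation. z lookup (`assign_z()`) minimizes the
distance between measured and calibration widths in `(sqrt(wx), sqrt(wy))`
space — the conventional metric for this calibration style — on a 1 nm grid
with parabolic refinement, and rejects fits farther than a configurable gate
(default 1.5 sqrt-nm) from the curve.

## Localization

Per frame: a difference-of-Gaussians band-pass (`filter_frame()`, default
sigmas 1 and 5 px) removes pixel noise and diffuse background; a constant
frame maps to exactly zero. The detection threshold is `k` times the robust
(MAD) standard deviation of the filtered frame (default `k = 5`) — a
scale-free choice that transfers across brightness levels, isolated in
`localize_params()`. Candidates are strict 8-neighborhood maxima;
candidates closer than `merge_dist` merge into the brighter one (split maxima
of one spot), and candidates whose fit windows overlap are *both* dropped —
the method assumes non-overlapping single-emitter images. Fits use a
pixel-integrated Gaussian plus constant background, least squares via
Levenberg–Marquardt: symmetric in 2D, independent x/y widths in 3D. Width
gates (default 0.3–3 × the calibration width range) and the off-curve z gate
reject mis-fits; every rejection is counted by reason in the table's
`rejections` attribute. The default 7×7 px window at 160 nm pixels covers
±3 sigma of the in-focus PSF.

Coordinates: continuous nm, origin at the FOV corner, pixel (1,1) centered
at (0.5 px, 0.5 px); stated in every molecule-list header.

## Drift correction

`estimate_drift()` reconstructs 2D images from frame bins (500–1000 frames
typical), cross-correlates each against the first bin's image (FFT, zero
padding, 3-point parabolic sub-pixel refinement; default 25 nm render pixel)
and reports a piecewise-linear trace with constant extrapolation beyond the
terminal bin centers. Bins whose correlation peak prominence falls below a
confidence floor raise an error advising larger bins. Axial drift is assumed
handled by the microscope's focus lock; a `dz` slot exists but defaults to
zero. `apply_drift()` shifts positions only — never counts, photons or z.

## Color coding and crosstalk

`assign_colors()` codes each localization by the activation pulse
immediately preceding its frame; all other frames are "nonspecific". Because
nonspecific activation is (by assumption) constant-rate across imaging
frames, `estimate_crosstalk()` measures the per-frame nonspecific rate from
the imaging frames *outside* the post-activation slots and subtracts its
expected contribution from each channel's apparent-specific count, floored
at zero. `subtract_crosstalk()` removes exactly the expected number of
contaminating localizations by seeded uniform random thinning within the
channel (plus an optional configured wrong-laser fraction for designated
channel pairs, e.g. 457 nm falsely activating the Cy3 pair). Uniform
thinning corrects *counts* without bias — the package frames "residual
crosstalk" as the net count excess over true specific events, which the
tests verify to be below 5% after correcting a 25% injected contamination —
but it cannot relabel any individual localization; spatially informed
subtraction is out of scope.

## Focal planes and mosaic

Within one FOV, planes taken at 300 nm focal steps overlap in z (the
detection range is ~800 nm). `align_focal_planes()` aligns planes laterally
by cross-correlating 2D reconstructions against the middle plane, then finds
each plane's z offset by correlating the 3D reconstructions (25 nm x/y,
50 nm z voxels) along z: the voxel-product correlation counts only
co-located structure, which also handles slanted processes whose 1D z
histograms would be featureless. Planes with an empty or structure-free
overlap are flagged for manual override rather than silently aligned.

Across FOVs, `pairwise_tile_offsets()` measures residual translations over
the nominal overlap of adjacent tiles (each unordered pair once;
the reverse direction is the exact negation). `solve_layout()` places all
tiles by equal-weight iterative relaxation: each tile repeatedly moves to
the mean position implied by its neighbors and the measured offsets, with
one anchor fixed. This relaxation is Gauss–Seidel on the normal equations of
the offset system, so its fixed point *is* the least-squares solution; the
default tolerance (1e-9 nm movement per sweep, capped at 10 000 sweeps)
iterates effectively to that fixed point, making consistent graphs exact.
Offsets marked `source = "manual"` in the offsets CSV are honored as hard
constraints (tiles joined by manual edges move as a rigid group).
Disconnected graphs are an error listing the components. Rotation and scale
are out of scope (stage tiles are translation-only).

## Rendering and resolution measurement

`render_storm()` accumulates unit-volume Gaussians so that image intensity
counts localizations (conservation is tested to 0.5%, kernels truncated at
4 sigma). The kernel width is either fixed or "theoretical":
`sigma = psf_sigma / sqrt(photons)`, the first-order localization
uncertainty; the background term is omitted for display purposes. Where a
quantitative expected precision is needed (e.g. the closed-form comparison
in the validation suite), `theoretical_precision()` provides the standard
pixelation- and background-corrected formula
`sigma^2 = (s^2 + a^2/12)/N + 8 pi s^4 b / (a^2 N^2)`. 3D stacks use 100 nm
slices. `localization_precision()`
pools recentred clusters of repeated single-label localizations and reports
the FWHM of a Gaussian fitted (maximum likelihood) per axis, requiring at
least 10 clusters of 5 localizations. `label_density()` divides region
counts by the region measure and by `n` localizations per label; regions
carry an explicit `measure_um` so densities can be defined per membrane
area rather than per bounding box.

## Study conditions used by the validation suite

The acceptance-level tests run the full simulate → localize → density →
resolution chain at the two label-density regimes of interest (680 and
2500 labels/µm²) on a 2 µm membrane tube (radius 40 nm) in a 22×10 px FOV at
160 nm pixels. Movie lengths (34 000 and 124 000 frames) were chosen from
the overlap-loss arithmetic so that the mean event rate stays near 0.04 per
frame: sparse, non-overlapping activation is the method's own operating
assumption, and at this rate ~91% of events survive the overlap/border/fit
gates, keeping the recovered Nyquist limit within a few percent of ground
truth. The X-junction fixture uses 25 nm-radius tubes (thin enough that each
tube's membrane projects to a single z mode after convolution with the
axial precision) at 300 nm separation. Localization precision is measured
on a grid of 30 isolated emitters (<1 min); the density runs take on the
order of a minute each on one CPU.

## Known limitations

* Single-emitter fitting only; overlapping-PSF multi-emitter fitting is out
  of scope, so localization recovery drops as the per-frame activation rate
  rises (quantified above).
* The camera model omits EM-gain excess noise; absolute precision values are
  therefore best-case for the given photon count.
* Crosstalk subtraction is count-unbiased but cannot identify which
  individual localizations are nonspecific.
* Calibration is field-invariant (no spatially varying PSF) and there is no
  refractive-index depth correction.
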