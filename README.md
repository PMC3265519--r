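# stormtrace

An R package implementing a complete analysis chain for **stochastic optical
reconstruction microscopy (STORM)** of membrane-labeled neural processes,
together with a synthetic-data simulator so that every stage can be exercised
and validated without microscope data.

STORM reconstructs a super-resolved image by iteratively activating a sparse
subset of photoswitchable fluorophores, localizing each emitter to nanometre
precision, and accumulating the localizations over tens of thousands of
camera frames. Tracing thin neural processes (axons, dendrites) through such
images requires not only high localization precision but also a high
*labeling density*: by the Nyquist sampling criterion, a structure labeled at
areal density *a* (labels/µm² in 2D, labels/µm³ in 3D) cannot be resolved
better than twice the mean spacing between labels,

```
alpha_Nyquist = 2 / a^(1/d)
```

and the final image resolution combines this label-density limit with the
localization precision (FWHM) in quadrature:

```
resolution = sqrt(alpha_Nyquist^2 + precision^2)
```

With a membrane-targeted label at ~2500 labels/µm² and ~18 nm lateral
precision this gives the ~44 nm 2D resolution regime in which small neural
processes become traceable.

## What the package does

| Stage | Functions |
|---|---|
| Simulate labeled structures & blinking | `structure_spec()`, `make_structure()`, `schedule_blinking()`, `render_frames()` |
| Astigmatism z-calibration | `build_calibration()`, `widths_at()`, `calibrate_from_stack()` |
| Localization (2D / astigmatic 3D) | `filter_frame()`, `find_peaks()`, `fit_peak_2d()`, `fit_peak_3d()`, `assign_z()`, `localize_movie()` |
| Drift correction | `estimate_drift()`, `apply_drift()` |
| Multicolor coding & crosstalk | `assign_colors()`, `estimate_crosstalk()`, `subtract_crosstalk()` |
| Focal planes & mosaic stitching | `align_focal_planes()`, `pairwise_tile_offsets()`, `solve_layout()`, `merge_mosaic()` |
| Rendering & resolution calculus | `render_storm()`, `line_profile()`, `localization_precision()`, `label_density()`, `nyquist_resolution()`, `combined_resolution()` |
| Orchestration | `pipeline_config()`, `run_pipeline()`, CLI at `inst/cli/smlm.R` |

## Worked example

Simulate an X-junction of two 25 nm-radius membrane tubes crossing with
300 nm axial separation, image it with an astigmatic PSF, localize in 3D and
measure the separation of the two z modes:

```r
library(stormtrace)

cal  <- astig_calibration()                      # wx/wy crossing at z0 = 0
spec <- structure_spec("x_junction", tube_radius = 25, z_separation = 300,
                       axis = c(2080, 2080, 0), label_density = 800,
                       arm_length = 1500)
em   <- make_structure(spec, seed = 5)
geo  <- stack_geometry(width_px = 26, height_px = 26, pixel_nm = 160,
                       n_frames = 16000)
tab  <- sim_localize(em, activation_schedule(),
                     blink_model(mean_localizations_per_label = 4,
                                 photons_mean = 5000),
                     geo, psf = cal, mode = "3d", seed = 7)

lo <- density(tab$z_nm[tab$z_nm < 0]); hi <- density(tab$z_nm[tab$z_nm >= 0])
hi$x[which.max(hi$y)] - lo$x[which.max(lo$y)]
#> [1] 293.0411        # two z modes separated by ~300 nm

resolution_report(2500, d = 2, precision_xy = 18)
#> resolution_report: a = 2500 labels/um^2 (n = 4)
#>   Nyquist limit   : 40.0 nm
#>   precision (xy)  : 18.0 nm FWHM
#>   resolution (xy) : 43.9 nm
```

The first number is the recovered axial separation of the two crossing
processes (ground truth: 300 nm); the report shows the resolution calculus at
the membrane-labeling density: a 40 nm Nyquist limit combined with 18 nm
precision gives a ~44 nm final 2D resolution.

## Conventions

* Lengths in nm; densities in labels/µm^d; widths are Gaussian sigmas in nm
  (FWHM = 2.355 sigma, converted via `sigma_to_fwhm()`).
* Molecule lists are CSV with header
  `frame,x_nm,y_nm,z_nm,photons,wx_nm,wy_nm,residual,channel,fov_id,pass_id`;
  coordinates are continuous, origin at the FOV corner, center of pixel
  (1,1) at (0.5 px, 0.5 px). `z_nm` is empty in 2D mode.
* Every stochastic step takes an explicit seed; pipeline runs write their
  resolved configuration and a manifest beside the outputs.
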