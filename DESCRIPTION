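Package: stormtrace
Title: STORM Localization Microscopy Analysis for Neural Process Tracing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A complete analysis chain for stochastic optical reconstruction
    microscopy (STORM) of membrane-labeled neural processes: spot detection and
    2D / astigmatic-3D elliptical Gaussian fitting of raw camera frames,
    z-calibration from bead scans, drift correction by image cross-correlation,
    activation-frame color coding with statistical crosstalk subtraction,
    alignment of focal planes and stitching of overlapping fields of view into
    a mosaic, Gaussian rendering, and the label-density / Nyquist resolution
    calculus that combines localization precision and labeling density in
    quadrature. Includes a synthetic-data simulator of blinking fluorophores on
    membrane-shell structures so every stage can be exercised and validated
    without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
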