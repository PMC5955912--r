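Package: olrkit
Title: Opto-Locomotor Reflex Assay: Stimulus Design, Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the opto-locomotor reflex (OLR) assay, in which a
    head-fixed mouse on a spherical treadmill views moving random dot
    patterns projected on the inside of a dome and its reflexive yaw is the
    behavioural readout. Provides isotropic spherical dot-field generation
    with a projector lookup table, condition grids and randomized interleaved
    session schedules, a synthetic cohort generator with known ground-truth
    tuning, trace preprocessing (boxcar smoothing, baseline subtraction,
    zero-speed correction and direction folding, across-mouse
    normalization), and inverse-variance-weighted polynomial curve and
    surface fitting with nested F-tests and bootstrap estimation of tuning
    peaks with confidence regions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
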