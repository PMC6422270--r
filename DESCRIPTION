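Package: artikin
Title: Speed-Curvature Power-Law Analysis of Articulatory Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for the analysis of the speed-curvature power
    law in repetitive tongue movements recorded by 3D electromagnetic
    articulography (EMA). Covers the full conditioning chain (two-stage FIR
    decimation, Horn rigid head-motion correction, zero-phase Butterworth
    filtering), analytic signal representation by penalized quintic
    regression splines and nine-point stencil differentiation, segmentation
    of continuous motion into closing and opening movements via the
    displacement principal component and velocity thresholds, per-movement
    kinematic triples (duration, amplitude, peak velocity) with the
    critically damped gesture model and its c factor, rate-stratified
    log-log power-law regression of tangential speed on 3D trajectory
    curvature (with a mid-sagittal 2D comparison), and phase-portrait
    density estimates with a fixed-point vs limit-cycle regime score. A
    synthetic-data module emulates the metronome-driven EMA paradigm with
    known ground truth so every stage is verifiable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    signal,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
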