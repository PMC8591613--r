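Package: opmpipe
Title: Movement-Robust Auditory Evoked Field Recovery for Wearable OPM-MEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for recovering auditory evoked fields from wearable
    optically-pumped-magnetometer (OPM) magnetoencephalography recordings made
    while the participant moves through the remnant field gradient of a
    magnetically shielded room. Includes a ground-truth-annotated synthetic
    recording generator (moving dual-axis sensor array in an affine room
    field), motion-capture rigid-body processing (gap interpolation,
    zero-phase filtering, Procrustes pose solving, kinematic summaries), an
    interference-suppression cascade (windowed motion regression, homogeneous
    field correction, spectral interpolation, zero-phase Butterworth
    filtering, automated artefact-segment rejection, epoching), an analytic
    spherical-conductor forward model with a symmetric source grid, and an
    LCMV beamformer with symmetric dipole pairs, neural-activity-index
    mapping, ROI virtual channels and pointwise statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
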