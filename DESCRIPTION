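Package: dbameg
Title: Deep-Brain MEG Source Localization Assessment with Minimum-Norm Operators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for assessing magnetoencephalography (MEG)
    source localization of subcortical generators. Builds a synthetic
    deep-brain-activity source model (cortex-like sheet, hippocampus-like
    tube, deep volume nuclei) with structure-specific dipole moment
    densities and orientation rules, computes spherical-conductor lead
    fields, constructs depth-weighted minimum-norm (wMNE), dSPM and
    sLORETA inverse kernels, analyses resolution-matrix point-spread and
    cross-talk functions, runs Monte Carlo dipole-localization-error
    experiments with controlled signal-to-noise ratio, and performs an
    alpha-band eyes-open versus eyes-closed contrast with FDR correction.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    signal
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
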