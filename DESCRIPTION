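Package: renalmpmri
Title: Multiparametric MRI Simulation and Quantification for Renal Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Digital-phantom simulation and quantitative analysis of
    multiparametric 1H MRI of renal lesions in a mouse model of tuberous
    sclerosis complex. Provides ellipsoidal lesion phantoms with
    tissue-class ground truth, forward simulators for multi-b-value
    diffusion, variable-flip-angle SPGR, T2-weighted fast spin echo and
    dynamic contrast-enhanced acquisitions (Rician noise), and the
    matching estimators: mono-exponential ADC mapping, DESPOT1 T1
    mapping, blood-normalized T2 intensity, semi-quantitative DCE
    parameters, Tofts-model K-trans fitting, slice-geometry-aware lesion
    volumetry with Bland-Altman agreement, and longitudinal response
    metrics with ADC-based lesion classification.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
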