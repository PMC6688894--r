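Package: cineqc
Title: Motion-Artefact Simulation and Quality Control for Cine Cardiac MR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated quality assessment of 2D+time cine cardiac
    magnetic resonance sequences. Provides a k-space corruption engine that
    synthesises mistriggering and respiratory (breathing) motion artefacts at
    graded severity, a beating-phantom generator for fully synthetic
    benchmarks, a temporal-Fourier/Hough-transform left-ventricle localizer
    with fixed-size ROI cropping, compact 3D-CNN and LRCN (CNN+LSTM)
    artefact classifiers trained by SGD with momentum, a severity-ordered
    baby-step curriculum training scheme with anti- and control-curriculum
    baselines, and evaluation utilities (confusion metrics, ROC/AUC,
    stratified k-fold cross-validation, variance-of-Laplacian blur scores).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
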