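Package: nirsubspace
Title: Random Subspace Ensemble Classification for fNIRS Brain-Computer
    Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for two-class functional
    near-infrared spectroscopy (fNIRS) brain-computer interfaces.
    Generates synthetic multi-channel, three-wavelength optical-density
    sessions with task-locked hemodynamic responses and physiological
    noise; converts optical density to oxy-/deoxy-hemoglobin
    concentration changes by the modified Beer-Lambert law; applies
    zero-phase Butterworth band-pass filtering, epoch segmentation and
    baseline correction; extracts windowed mean (AVG) and slope (SLP)
    features; trains random-subspace ensembles of linear discriminant
    weak learners with majority voting alongside full-feature strong
    learners (linear SVM, LDA); and compares classifiers by repeated
    stratified k-fold cross-validation with the variance-corrected
    t statistic and Benjamini-Hochberg false-discovery-rate control.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    MASS,
    nortest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
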