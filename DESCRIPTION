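Package: sersdx
Type: Package
Title: AI-Assisted SERS Spectral Diagnostics for Serum Exosome Liquid Biopsy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for label-free surface-enhanced Raman (SERS) spectral
    diagnostics of serum exosomes. Provides a synthetic cohort simulator with
    planted band-level disease effects, a Raman preprocessing chain
    (cosmic-ray removal, asymmetric-least-squares baseline correction,
    Gaussian smoothing, min-max normalization), a one-dimensional
    convolutional network with a stacked multilayer-perceptron probability
    refiner trained under grouped five-fold cross-validation, per-sample
    probability aggregation with confusion-matrix/ROC evaluation, and an
    interpretability layer offering gradient- and weight-based feature
    importance, differential spectra, and internal-reference peak-ratio
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    data.table,
    jsonlite,
    ggplot2,
    rlang
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
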