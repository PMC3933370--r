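Package: lungmorph
Title: Morphological Complexity Analysis and Classification of Lung Sounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: End-to-end analysis of single-channel chest auscultation
    recordings for discriminating normal from abnormal lungs. Provides
    enhancement of lung-sound recordings (first-order differencing and
    empirical-mode-decomposition based heart-sound suppression),
    respiratory-cycle segmentation from the smoothed Hilbert envelope,
    per-cycle morphological complexity features (excess kurtosis, skewness,
    gliding-box lacunarity and sample entropy), and classification with an
    extreme learning machine or a radial-basis-function support vector
    machine evaluated by stratified k-fold cross-validation. A seeded
    synthetic lung-sound generator with ground-truth cycle boundaries,
    adventitious sound events and heart-sound mixtures supports testing and
    benchmarking when clinical recordings are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    e1071,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    kernlab,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
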