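Package: engagefuse
Title: Multimodal Biosignal Fusion for Driver Mental-Engagement Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for classifying driver mental engagement from
    synchronized EEG, skin potential response (SPR) and ECG recordings sampled
    at 200 Sa/s. Provides readers and writers for the synchronized recording
    format with dropped-sample repair, a seeded synthetic cohort generator with
    engagement-dependent spectral, cardiac and electrodermal structure plus
    realistic artifacts, the full cleaning chain (Butterworth notch, FIR EEG
    band-limiting, artifact subspace reconstruction, two-channel SPR local
    energy fusion, ECG lead selection and high-pass filtering, obstacle-window
    excision, fixed-length segmentation and labeling), two deep convolutional
    fusion classifiers (a data-level fusion network and a multi-branch
    feature-level fusion network) trained with Adam and early stopping, and
    leave-one-subject-out evaluation with accuracy, sensitivity, specificity,
    balanced accuracy and geometric mean.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    optparse
Config/testthat/edition: 3
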