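Package: serpbci
Title: Decoding Selective Tactile Attention from Somatosensory Event-Related Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation, preprocessing and decoding pipeline for an
    electrotactile brain-computer interface based on somatosensory
    event-related potentials (sERPs). Generates synthetic multi-channel EEG
    with attention-modulated sERP components, band-pass filters and epochs
    recordings, rejects ocular/movement artifacts, averages trials and
    assembles multi-channel feature vectors, selects features by wrapper-based
    sequential forward selection inside a nested cross-validation, evaluates
    five classifier families (logistic regression, k-nearest neighbours,
    support vector machine, random forest, multilayer perceptron) over their
    hyperparameter grids, and summarises accuracy, feature-selection maps,
    cross-condition significance and information transfer rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    class,
    e1071,
    glmnet,
    jsonlite,
    randomForest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
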