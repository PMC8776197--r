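Package: eegscape
Title: Band-Resolved EEG Feature Extraction and Landscape-Perception Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for stimulus-locked
    multichannel EEG decoding of perceived landscape categories. Generates
    synthetic 32-channel recordings with a seven-class block design,
    1/f background, band-limited oscillations, eye-blink and line-noise
    artifacts; preprocesses them (linked-mastoid re-referencing, detrending,
    anti-aliased downsampling to 250 Hz, zero-phase 0.5-70 Hz band-pass,
    ICA or regression artifact removal, 2-s epoching with amplitude
    rejection); extracts six feature families per frequency band (mean
    amplitude spectrum, power spectral density, differential entropy, and
    the DASM/RASM hemispheric-asymmetry and DCAU fronto-caudal contrasts);
    and evaluates per-subject seven-class decoding with back-propagation
    neural network, k-nearest-neighbour, random-forest and linear
    support-vector classifiers under stratified 10-fold cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    class,
    e1071,
    ranger,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
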