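Package: focimap
Title: Dynamic Brain-Network Mapping and Epileptic-Focus Localization from
    Multichannel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps short-term (mutual information) and long-term
    (nonlinear-feature T-index) synchronization across multichannel scalp
    EEG, builds thresholded brain networks per sliding window, and
    localizes candidate epileptic foci as maximum-degree core nodes
    tracked across awake, sleep and ictal stages. Includes band-pass
    preprocessing, phase-space feature extraction (correlation dimension,
    approximate entropy, Hurst exponent, PCA eigenvalue-spread index), a
    synthetic multichannel EEG generator with planted stage-dependent
    coupling for method validation, and an end-to-end localization
    pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    signal,
    deSolve,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
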