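Package: neurowatt
Title: Energy-Aware Comparison of EEG Seizure Detectors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing and comparing energy-efficient EEG seizure
    detectors intended for implantable responsive neurostimulation devices.
    Provides a synthetic annotated EEG generator, the signal-conditioning
    chain used for subgaleal-style four-channel montages (Chebyshev type-II
    bandpass, 1 mV artifact rejection, central re-referencing), a 16-feature
    time/frequency-domain extractor, three patient-specific classifiers
    (random forest, convolutional neural network, LSTM recurrent network),
    a platform-independent energy model that counts arithmetic operations
    and memory accesses per classification, and the seizure-detection
    evaluation protocol (window-level AUCs, early-seizure variants,
    event-level sensitivity, false-detection rate with 5 s deduplication,
    detection delay, and leave-one-seizure-out cross-validation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    ranger,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
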