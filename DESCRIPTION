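Package: neuroauth
Title: Chronic EEG Biometric Authentication with Bagged LSTM Weak Learners
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying electroencephalography (EEG) based biometric
    authentication under chronic (multi-day) recording conditions. Implements
    a complete decoding pipeline: Butterworth band-pass filtering,
    downsampling and epoching of multi-channel recordings; short-time Fourier
    transform sub-band power features; a shallow long short-term memory
    (LSTM) binary authenticator trained by backpropagation through time;
    bootstrap aggregating (bagging) with majority voting; per-subject
    enrollment with balanced imposter sampling and multi-task decision
    combination; and a leave-one-day-out evaluation harness reporting
    authentication accuracy, false acceptance rate (FAR) and false rejection
    rate (FRR), with training-fraction and ensemble-size sweeps and Wilcoxon
    signed-rank comparisons. Ships a seeded synthetic multi-subject,
    multi-day EEG cohort generator with subject-specific spectral
    fingerprints and event-related desynchronization, so the full pipeline
    is testable without access to real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: C++17
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
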