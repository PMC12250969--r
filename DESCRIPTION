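Package: mvbnsleep
Title: Multi-View Brain-Network Sleep Staging for Neonatal EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stages neonatal sleep (wakefulness, active sleep, quiet sleep)
    from 8-channel EEG by converting each 30-second epoch into a multi-view
    functional brain network -- Pearson correlation, mutual information,
    phase-locking value, phase-lag index and a phase-instability index,
    computed on the broadband signal and on canonical rhythm bands -- and
    classifying the stacked connectivity matrices with a lightweight
    convolutional network preceded by a trainable per-view attention
    weighting and an optional channel mask. Includes EDF input/output,
    zero-phase Butterworth preprocessing, a seeded synthetic-EEG generator
    whose stage labels are encoded in cross-channel coupling structure,
    leave-one-subject-out and subject-wise k-fold evaluation protocols, and
    a full multiclass metric suite.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
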