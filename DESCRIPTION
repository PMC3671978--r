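Package: ssvepbci
Title: Phase-Tagged SSVEP Brain-Computer Interface Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and decoding toolkit for phase-tagged steady-state
    visual evoked potential (SSVEP) brain-computer interfaces. Four visual
    flickers share one 20 Hz flicker frequency but carry distinct phase tags;
    the gazed target is decoded from the amplitude and phase of the 20 Hz
    component of single-channel occipital EEG. The package provides a
    synthetic Oz-EEG generator with phase-locked SSVEP and band-limited
    background noise, sliding Hamming-window Fourier feature extraction after
    causal Butterworth band-pass filtering, Z-test cleaning of training
    vectors, a one-against-all multiclass support vector machine over the
    (amplitude, phase) feature plane, Kolmogorov-Smirnov-gated effective-epoch
    detection with plurality voting for online command output, a
    cycle-average phase-template baseline detector, and Wolpaw
    information-transfer-rate metrics with session-level reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    signal,
    e1071,
    withr,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
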