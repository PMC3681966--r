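Package: gammasync
Title: Gamma-Band Time-Frequency, Phase Synchrony and Decoding Analysis of
    Perceptual-State EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for studying gamma-band signatures of
    emergent visual perception in multi-channel EEG. Provides smoothed pseudo
    Wigner-Ville time-frequency estimation on a 1 Hz grid with baseline
    z-normalization, all-pairs inter-trial phase-locking value and imaginary
    coherency, band-wise nonparametric contrasts with step-down Holm
    correction, and linear support-vector decoding of perceived versus
    unperceived trials with label-permutation significance. Includes a
    synthetic EEG generator emulating rapid-serial-presentation and
    rotating-stimulus paradigms (1/f background, von Mises phase-coupled
    narrow-band bursts, zero-lag volume-conduction mixing, ocular artifacts)
    so every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
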