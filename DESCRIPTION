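Package: preshot
Title: Pre-Shot EEG Band-Power Dynamics Across Performance States
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for event-locked EEG recorded during
    self-paced precision shooting. Computes event-related
    desynchronization/synchronization (ERD/ERS) percentage maps in the
    theta, low-alpha and high-alpha bands from Hilbert-envelope band
    power referenced to a pre-shot baseline, categorizes trials into the
    four multi-action-plan (MAP) performance quadrants from shooting
    score and perceived control, and tests quadrant-by-time effects per
    electrode with repeated-measures ANOVA (Huynh-Feldt sphericity
    correction, partial eta squared, Fisher LSD post-hocs). Includes a
    synthetic session generator with known injected band-power
    modulations so every stage is verifiable, EDF and tabular I/O, and
    topographic map interpolation on the 10-20 montage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    ggplot2
Config/testthat/edition: 3
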