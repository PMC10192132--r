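Package: hfdeeg
Title: Higuchi Fractal Dimension Analysis of Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Nonlinear complexity analysis of multichannel EEG built around
    the Higuchi fractal dimension (HFD): a calibrated synthetic cohort
    generator with channel-localised group effects (spectral synthesis of
    power-law noise), whole-signal and windowed HFD feature extraction, a
    spread-based k_max tuning procedure, channel-level expert-vs-novice
    contrasts with resting-state and presentation-style controls, and
    two-group classification under subject-presentation, subject-specific
    and presentation-specific cross-validation splits with a fixed
    classifier grid, including a high-density versus standard 10/20
    montage comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    data.table,
    class,
    e1071,
    rpart
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
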