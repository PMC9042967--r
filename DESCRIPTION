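Package: surgskill
Title: Continuous Bimanual Surgical Skill Scoring from Simulator Streams
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts raw bimanual surgical-simulator recordings (50 Hz
    instrument tip positions, applied forces, pedal activation and tissue
    state) into sixteen performance metrics on a 0.2 s grid, trains a
    two-layer sequence-to-sequence LSTM regressor on two-end expertise
    labels (+1 expert, -1 novice) to emit a continuous expertise score five
    times per second, and inverts the same architecture for metric-level
    coaching and bleeding / tissue-injury risk prediction. Includes a
    synthetic bimanual-motion simulator with a controllable ground-truth
    skill parameter, a participant-grouped train/validation/test splitter,
    and a statistical validation harness (one-way ANOVA with Tukey-Kramer
    post hoc, assumption checks, training-year regression).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    car,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
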