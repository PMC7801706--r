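Package: microstatr
Title: EEG Microstate Segmentation, Features and Task-Performance Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for EEG microstates in a two-group cognitive-task
    design: preprocessing (band-pass filtering, common-average re-referencing,
    fixed-length epoching, threshold artifact rejection), polarity-invariant
    modified k-means segmentation into the four archetype microstates (A-D)
    selected by global explained variance, extraction of 36 per-epoch features
    (18 microstate, 12 transition percentages, 6 directional predominances with
    a run-shuffling permutation test), Mann-Whitney group comparisons with
    Bonferroni-Holm correction, and a recursive-feature-elimination
    classification harness with eight classifiers and five-fold
    cross-validation. Includes a synthetic multichannel EEG generator with
    known Markov microstate structure so every stage is testable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    data.table,
    signal,
    e1071,
    randomForest,
    class
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
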