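Package: densernn
Title: Densely Connected Recurrent Networks for Longitudinal Disease-Progression Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts a patient's next-visit disease-severity score (MDS-UPDRS,
    0-272) from high-dimensional longitudinal transcriptomic and clinical
    features using a densely connected, batch-normalized deep recurrent
    network. Provides a synthetic longitudinal RNA-seq cohort simulator,
    cohort readers/writers with leakage-safe feature scaling and
    variable-length history-window construction, the dense recurrent
    architecture (composite blocks, dense blocks, vanilla/GRU/LSTM cells)
    with exact reverse-mode gradients and a Nadam optimizer, same-length
    mini-batching with a plateau learning-rate schedule, progression
    identification error/correlation (PIE/PIC) evaluation with subject-level
    cross-validation, visit-aggregation classical baselines, and the
    statistical comparison utilities (fold-wise and summary t-tests,
    instrument-noise floor).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    e1071,
    rpart,
    randomForest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
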