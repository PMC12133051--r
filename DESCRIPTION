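Package: setconform
Title: Conformal Risk Control for Multiclass Prediction Sets with
    False-Negative-Rate Guarantees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts multiclass classifier score matrices (for example,
    softmax outputs of RNA-seq cancer-subtype classifiers) into prediction
    sets with a user-specified, statistically guaranteed false-negative-rate
    (FNR) tolerance via split conformal risk control. Provides calibration of
    an FNR-controlling score threshold, prediction-set formation, empirical
    error-rate selection, repeated shuffle-split cross-validation of the
    guarantee, stratified evaluation against uncalibrated baselines, a
    synthetic score-matrix generator emulating imbalanced confusable-subtype
    classifier output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    withr,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
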