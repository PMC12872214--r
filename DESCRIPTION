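Package: linkehr
Title: Deterministic, Probabilistic, and Machine Learning Record Linkage
    for Deidentified EHR Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Links deidentified patient records across two electronic
    health record extracts that share no direct identifier. Implements
    rule-based deterministic matching, Fellegi-Sunter probabilistic
    linkage with expectation-maximization estimation of m- and
    u-probabilities, log2 agreement weights and one-to-one assignment,
    and machine-learning pair classification (k-nearest neighbours,
    logistic regression, neural network, random forest) with bootstrap
    performance estimation. A synthetic two-source cohort generator with
    configurable per-field corruption and a clone-and-deidentify
    simulation harness allow every method to be evaluated against known
    ground truth via confusion-matrix metrics (sensitivity, PPV, F1,
    Wilson 95% confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    class,
    nnet,
    randomForest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
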