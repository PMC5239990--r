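Package: rfrs
Title: ReliefF and Rough-Set Hybrid Feature Selection with Boosted Tree Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid classification workflow for tabular clinical decision tables:
    equal-interval discretization of continuous attributes, ReliefF feature weighting
    with probabilistic handling of missing values, genetic-algorithm search for
    rough-set reducts guided by the ReliefF weights, and evaluation of each reduct
    with a boosted ensemble of C4.5-style decision trees. Reports confusion-matrix
    metrics (sensitivity, specificity, accuracy), ROC curves and AUC under repeated
    stratified train/test splits or leave-one-out (jackknife) validation. Includes a
    synthetic decision-table generator with planted relevant, redundant and noise
    attributes so ground-truth minimal reducts are known by construction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
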