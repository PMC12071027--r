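Package: milanova
Title: Weakly Supervised Multiclass Histopathology Bag Classification and
    Factorial Hyperparameter Sensitivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a multiclass multiple-instance-learning classifier for
    whole-slide-image patch-feature bags in the WELDON/CHOWDER family: per-patch
    per-class attention scores from a stack of shared-weight one-dimensional
    convolutions, MinMax selection of the top-scoring instances plus negative
    evidence, and a multilayer-perceptron head, trained with dropout and weight
    decay. Around the classifier it provides the full hyperparameter-sensitivity
    pipeline: synthetic class-conditional feature-bag and factorial results-table
    generators, factorial experiment execution with macro F1 and one-vs-rest AUC
    responses, outlier screening (studentized values, MAD-based modified Z-scores,
    Grubbs' test, hard metric thresholds), logit transformation, Type III
    sum-of-squares main-effects ANOVA with residual diagnostics, and Fisher LSD
    multiple range tests with least-squares means and homogeneous-group letters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    car
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    pROC,
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
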