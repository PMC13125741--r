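Package: fbinfer
Title: Exact Inference and Power Analysis for F-beta Classification Scores
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exact small-sample statistical inference for the F1 score and its
    generalization, the F-beta score, of binary classifiers. Models the
    true-positive and false-positive counts of a confusion matrix as
    independent binomials, calibrates the per-negative false-positive rate so
    the expected estimated score matches a target, and enumerates the exact
    discrete distribution of the estimated score. Provides equal-tail
    confidence intervals, minimum-tail exact hypothesis tests (point nulls,
    benchmark nulls via a supremum over the iso-F-beta curve), and analytic
    power and sample-size calculations, for a single classifier and for the
    difference between two independent classifiers evaluated on a shared test
    set. Delta-method normal approximations with automatic exact-versus-normal
    selection keep large problems tractable. Includes a seeded simulation
    harness for coverage, size and power studies, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
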