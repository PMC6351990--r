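Package: comprehIRT
Title: Item Response Theory Measurement of EHR Note Comprehension
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for measuring electronic health record (EHR) note
    comprehension with a single-factor three-parameter logistic (3PL) item
    response theory model. Provides response-probability and likelihood
    functions, maximum-likelihood and expected-a-posteriori ability
    estimation with Fisher-information standard errors, marginal
    maximum-likelihood (EM) item calibration with rule-based bank filtering,
    a synthetic-cohort generator emulating a three-arm randomized
    comprehension study with attention-check items, and an analysis pipeline
    covering quality-control filtering, raw scoring, Welch arm comparisons,
    demographic tabulation and score regression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
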