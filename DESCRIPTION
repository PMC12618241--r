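Package: tiadapt
Title: Asymmetric Reinforcement Learning and Changepoint Adaptation in
    Transitive Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how asymmetric value updating shapes
    transitive inference (TI) and its adaptation to changes in relational
    structure.  Simulates a seven-item TI task with a mid-session rank
    changepoint, implements a family of Rescorla-Wagner value-learning
    agents with symmetric, asymmetric, phase-dependent and
    preference-adaptive learning rates, fits them to trial-level choice
    data by maximum likelihood with a bounded differential-evolution
    optimizer, compares them with random-effects Bayesian model selection
    (protected exceedance probabilities), and computes the behavioural
    signatures of asymmetric learning: value compression, symbolic
    distance effects, anchor-preference shifts and changepoint-direction
    asymmetries.  Includes a synthetic-cohort generator and model and
    parameter recovery suites.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
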