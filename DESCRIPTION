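Package: bartjoint
Title: Joint Hierarchical Bayesian Modelling of BART Behaviour and
    Structural Network Fractional Anisotropy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a joint hierarchical Bayesian model linking risky-choice
    behaviour on the Balloon Analogue Risk Task (BART) to white-matter
    structural connectivity summarised as Network Fractional Anisotropy
    (FA).  A cognitive model with risk propensity, behavioural consistency
    and a dynamic subjective burst probability generates pump/cash action
    sequences; logit-normal models describe the FA of tracts in two
    fronto-striatal networks; individual-level cognitive and neural
    parameters share a multivariate Student-t prior with a structured
    covariance matrix.  Includes an adaptive Metropolis-within-Gibbs
    sampler, Gelman-Rubin convergence diagnostics, posterior predictive
    checks, a full synthetic-data generator for the task and cohort, and
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
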