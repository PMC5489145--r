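Package: jurybayes
Title: Bayesian Models of Judgment Adaptation Under Social Influence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and model-based analysis of judgment adaptation in a
    jury decision task, where people revise a punishment judgment after seeing
    the average judgment of a small or large group. Implements three competing
    trial-level models of judgment change: Bayesian precision-weighted belief
    fusion whose predicted change is the Kullback-Leibler divergence between
    prior and posterior beliefs, a linear conformity regression, and a surprise
    (unexpectedness) model. Provides per-subject constrained maximum-likelihood
    fitting with a profiled scale and error variance, leave-one-out
    cross-validation, BIC model comparison, a parameter-recovery harness, the
    relative-credibility statistic delta-sigma, descriptive conformity metrics,
    and a generic single-coefficient time-course likelihood comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
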