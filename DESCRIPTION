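Package: gsbayes
Title: Approximate Bayesian Whole-Genome Regression with Marginal HPD
    Significance Tests
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits whole-genome regression models for additive, dominance and
    pairwise epistatic marker effects under a spike-plus-Laplace prior using a
    marginalized Gauss-Seidel scheme with closed-form one-locus posterior
    means.  Provides a marginal significance test for every fitted effect
    based on the credibility of the highest-posterior-density interval
    tangent to zero (measure of evidence) as well as a marginal Bayes factor.
    Includes a forward-in-time population simulator producing linked SNP
    panels with half-sib family structure and traits with additive, dominance
    and epistatic architecture, plus evaluation utilities (sensitivity and
    specificity against simulated causative variants, explained genetic
    variance, prediction accuracy, and resampling-based hyperparameter
    tuning).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
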