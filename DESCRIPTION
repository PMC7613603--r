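Package: pairjmm
Title: Pairwise Pseudo-Likelihood Joint Models for Clustered Binary Outcomes
    with Multilevel Multiple Imputation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint modelling of many correlated binary quality-of-care
    outcomes observed on patients nested in clinicians, fitted by the
    pairwise (composite-likelihood) strategy: all bivariate logistic
    random-intercept models are estimated by maximum likelihood with
    adaptive Gauss-Hermite quadrature, stacked, averaged with a weight
    matrix, and equipped with a cluster-robust sandwich covariance.
    Partially observed patient- and clinician-level categorical covariates
    are multiply imputed with a two-level latent-normal joint model fitted
    by Gibbs sampling, and per-imputation estimates are pooled by Rubin's
    rules with joint Wald tests across outcomes. Includes a synthetic-data
    generator emulating a cluster-randomized pneumonia-care trial
    (hospitals, clinicians, patients, nine binary indicators, missing-at-
    random covariates), assembly of the full random-intercept
    variance-covariance matrix from pairwise blocks, and principal
    component summaries of the between-outcome associations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
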