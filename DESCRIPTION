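Package: phyloweber
Title: Joint Phylogenetic-Psychophysical Modelling of Quantity Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers species-level Weber fractions from binary
    quantity-discrimination trials with a joint hierarchical Bayesian model:
    a latent per-trial log Weber fraction built from a species-level
    predictor regression, phylogenetically correlated species effects
    (Pagel's lambda mixing of a tree-derived correlation matrix with the
    identity), and study, subject and task random effects, linked to trial
    accuracy through the linear-scale scalar-variability psychophysical
    model. Fitting is by the no-U-turn sampler over an analytic
    log-posterior gradient. Includes tree utilities (grafting calibrated
    splits, phylogenetic correlation matrices, PGLS residuals), predictor
    table construction with allometric imputation, a synthetic-data
    generator matching the model's generative structure, convergence
    diagnostics and posterior reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nlme,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
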