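Package: taintsel
Title: Genomic Evaluation of Boar-Taint Compounds in Pigs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Genomic prediction of skatole and androstenone fat
    concentrations in intact male pigs. Implements a SNP-derived genomic
    relationship matrix with heterozygosity-based diagonals, GBLUP fitted by
    restricted maximum likelihood, five Bayesian whole-genome regression
    models (Bayes A, Bayes B, Bayes C, stochastic search variable selection
    and the Bayesian Lasso) fitted by Gibbs sampling with data-driven
    hyperparameters under bounded flat priors, heritability estimation from
    posterior chains, pair-preserving cross-validated prediction accuracy, a
    single-QTL baseline predictor, and a synthetic-data generator emulating a
    discordant littermate case-control design with SNP and individual
    quality control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
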