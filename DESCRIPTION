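Package: ssgp
Title: Single-Step Genomic Prediction and Bayesian Whole-Genome Regression
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Genomic prediction of breeding values for populations in which only a
    subset of animals is genotyped. Implements the numerator relationship matrix
    (tabular method), VanRaden-type genomic relationship matrices with mean scaling
    to the pedigree block and iterative SNP reweighting, single-step GBLUP via the
    combined H matrix, Gibbs samplers for BayesB, BayesC and BayesC-pi
    whole-genome regression, and their single-step extensions with explicitly
    imputed genotype covariates and imputation residuals. Includes pedigree-aware
    K-means cross-validation, accuracy and bias metrics, window-variance GWAS from
    posterior draws of marker effects, and a gene-dropping simulator for
    genotyped/non-genotyped multi-generation populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
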