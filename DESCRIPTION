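Package: gxePredict
Title: Genomic Prediction of Lifespan Across Environments with
    Gene-Environment Interaction Kernels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Kernel-based genomic prediction for multi-environment panels of
    fully inbred lines, motivated by lifespan variation in the Drosophila
    Genetic Reference Panel measured in both sexes at three temperatures.
    Builds the VanRaden genomic relationship matrix, an environmental
    similarity kernel from sex and temperature covariates, and their Hadamard
    interaction kernel; fits the nested G-BLUP, E-BLUP, GE-BLUP and
    GxE-BLUP mixed models by restricted maximum likelihood (average
    information algorithm) with BLUP prediction and variance partitioning; a
    Bayesian multi-trait model (one trait per environment) by Gibbs sampling
    with cross-environment genetic correlations; and a Legendre-polynomial
    random-regression (reaction norm) model. Includes three cross-validation
    schemes (random lines, random observations, new environment) and a
    synthetic-data generator with exactly specified variance composition.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools, Rcpp, jsonlite, yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
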