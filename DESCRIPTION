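Package: ovipred
Title: Pedigree and Genomic Prediction for Multi-Breed Sheep Populations
Version: 0.1.0
Authors@R: person("Ovipred", "Developers", email = "ovipred@example.org",
    role = c("aut", "cre"))
Description: Tools for genomic selection in multi-breed livestock populations,
    modelled on Australian sheep resource flocks. Provides a synthetic
    multi-breed data generator (Balding-Nichols breed divergence, gene-drop
    genotypes with Haldane recombination, four-class mixture marker effects),
    SNP and animal quality control with mean-dosage imputation, pedigree (A)
    and genomic (G) relationship matrices with breed-composition regressors,
    REML variance-component estimation and Henderson mixed-model (BLUP/GBLUP)
    solvers, a four-component normal-mixture Bayesian marker model (BayesR)
    Gibbs sampler, and across-sire-family cross-validation with accuracy,
    bias and relatedness summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    data.table
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation
Config/testthat/edition: 3
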