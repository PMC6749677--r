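Package: semgwas
Title: Trait Networks and Structural Equation Models for Multi-Trait GWAS
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for network-guided multi-trait genome-wide association
    analysis. Fits a Bayesian multi-trait genomic best linear unbiased
    prediction (MT-GBLUP) model by Gibbs sampling to separate phenotypes into
    genetic values and residuals, learns a directed acyclic trait network from
    the genetic values by score-based hill climbing with bootstrap model
    averaging, scans SNPs with a multivariate generalized least squares
    association model (MTM-GWAS), and re-expresses each SNP effect under the
    learned network as a structural equation model (SEM-GWAS) that partitions
    the total effect on every trait into a direct effect and indirect effects
    transmitted through upstream traits. Includes PLINK and dosage-matrix
    readers, a genomic relationship matrix builder, a recursive-trait
    simulator for validation, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
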