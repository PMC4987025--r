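Package: famvc
Title: Family-Based Variance Components, Genetic Correlations, and
    Polygenic Risk Scores for Complex Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pedigree-based mixed-model analysis of complex traits in family
    cohorts. Builds the additive (numerator) relationship matrix and
    shared-environment covariance structures (spouse, sibship, household)
    from a pedigree; estimates variance components by average-information
    REML and by a probit threshold-model Gibbs sampler for ordinal and
    binary traits, with DIC- and likelihood-ratio-based stepwise selection
    of shared-environment effects; fits bivariate models partitioning the
    covariance between two traits into genetic and shared-environment parts
    with constrained-null likelihood-ratio tests; and computes polygenic
    risk scores from GWAS summary statistics at p-value thresholds, with
    relatedness-aware association and variance-explained estimates. A
    gene-dropping simulator generates multigenerational family cohorts with
    known variance-component ground truth, genotypes, and training-GWAS
    summary statistics for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
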