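Package: cpmeta
Title: Cross-Phenotype Meta-Analysis of GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("cpmeta", "developers", role = c("aut", "cre"),
    email = "cpmeta@example.org")
Description: Combines genome-wide association summary statistics across
    cohorts and phenotypes while accounting for the correlation of test
    statistics induced by overlapping or related samples and by trait
    correlation.  Implements the homogeneous-effect combined statistic
    (S_Hom, chi-squared with one degree of freedom) and the
    heterogeneous-effect truncated max statistic (S_Het) with a Monte
    Carlo null and beta-tail approximation, estimation of the
    between-panel correlation matrix from LD-pruned null SNPs, a
    conventional sample-size-weighted Z meta-analysis baseline, genomic
    control, locus identification with flanking windows, and a synthetic
    summary-statistics generator with known ground truth for power and
    calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    data.table,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
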