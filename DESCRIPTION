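Package: snpdiv
Title: SNP Panel Design and Genetic Diversity Analysis for Germplasm Collections
Version: 0.1.0
Authors@R: person("A.", "Analyst", email = "analyst@example.org",
    role = c("aut", "cre"))
Description: Tools for developing genome-wide panels of biallelic SNP
    markers from variant files and analysing the genetic diversity and
    population structure of germplasm collections genotyped with them.
    Covers panel selection (even genome spacing, flank isolation, minor
    allele frequency), a post-genotyping quality-control filter cascade,
    expected and observed heterozygosity, pairwise multilocus matching
    for synonym and hybrid discrimination, allele-sharing distances with
    UPGMA clustering and principal coordinate analysis, hierarchical
    analysis of molecular variance and pairwise F_ST with permutation
    tests, and a Gibbs-sampler implementation of admixture-model
    clustering with Evanno delta-K model selection. Includes an F-model
    genotype simulator so the whole pipeline can be exercised on
    synthetic data with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
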