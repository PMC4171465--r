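Package: fanovaseq
Title: Functional Analysis of Variance for Region-Based Genetic Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Region-based association testing for case-control sequencing data
    by functional analysis of variance (FANOVA). Genotype profiles of a genomic
    region are smoothed into curves with cubic B-splines (fixed small basis,
    unpenalized large basis, or penalized splines with per-subject smoothing
    selected by generalized cross validation), optionally after a flip-minimizing
    genotype relabeling that reduces 0-2 oscillations induced by negative
    linkage disequilibrium. Mean genotype curves are compared across phenotype
    groups with an F-type statistic whose null is approximated either by a
    Satterthwaite-adjusted F distribution or by permutation of a pairwise
    distance matrix. A scalar-on-function linear model (FLM) Wald test is
    included as a comparator, together with a synthetic sequencing-data
    simulator (latent AR(1) haplotype copula, mixed rare and common allele
    frequencies, logistic disease models) for size and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
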