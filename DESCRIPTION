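Package: erodiv
Title: Private-Variant Uniqueness, Haplotype Networks and Diversity
    Estimators for Detecting Genetic Erosion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying genetic erosion in predominantly selfing
    crops from multi-sample variant data and organellar alignments.
    Implements per-sample private-variant proportions (private doubleton
    SNPs and private homozygous indels) with depth-threshold robustness
    sweeps, z-scores and modified Thompson Tau outlier detection;
    identity-by-state duplicate pruning; nucleotide and haplotype
    diversity with pairwise-deletion handling of gaps and ambiguities;
    rarefied allelic richness; median-joining haplotype networks with
    haplogroup assignment and divergence dating; group-level variant
    partitioning, diagnostic domestication-allele scoring, permutation
    tests for physical clustering of group-specific SNPs, and genotype
    PCA. A synthetic-data generator emulates wild/domesticated/ancient
    cohorts with planted truth so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
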