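Package: allelic
Title: Population Genomic Diversity, Differentiation and Conservation
    Prioritisation from SNP Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for range-wide conservation genomics of structured
    populations from biallelic SNP genotype matrices: a post-genotyping
    quality-control cascade (locus call rate, minor allele count, excess
    heterozygosity, kinship-based removal of close relatives, sliding-window
    linkage-disequilibrium pruning, sample missingness and technical-replicate
    concordance), per-population diversity accounting (allele counts,
    effective alleles, small-sample-corrected heterozygosities, autosomal
    heterozygosity over callable sites, inbreeding coefficients),
    Prevosti-distance ordination and dendrograms, pairwise Weir-Cockerham
    F_ST with locus bootstrap, linkage-disequilibrium-based effective
    population size trajectories with individual-dropout bootstrap, rarefied
    allelic richness with leave-one-out population contributions, and
    resampled maximum-coverage selection of populations that jointly retain
    the largest share of the species' alleles.  Includes a hierarchical
    Balding-Nichols genotype simulator and a forward Wright-Fisher simulator
    with recombination so every estimator can be validated against known
    truth without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
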