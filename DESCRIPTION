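Package: equimhc
Title: Equine MHC Microsatellite Diversity, Trio Phasing and Meiotic Event Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of major histocompatibility complex (MHC) microsatellite
    panels in pedigreed horse populations. Provides trio-based multi-locus
    haplotype phasing by Mendelian constraint propagation, classification of
    meiotic genetic events (crossover, gene conversion, repeat-unit insertion
    and deletion) with per-meiosis frequencies and new-haplotype ratios, the
    standard microsatellite diversity panel (observed and unbiased expected
    heterozygosity, polymorphism information content, Fis, rarefacted allelic
    richness, effective and private alleles, null-allele frequency,
    Hardy-Weinberg exact tests, genotypic linkage-disequilibrium tests,
    chi-square allele-frequency homogeneity), between-population
    differentiation (Nei identity and distance, pairwise PhiPT/Fst,
    hierarchical AMOVA with permutation tests), Evanno delta-K
    post-processing of clustering likelihoods, Genepop import and export, and
    a forward pedigree simulator with a machine-readable truth log for
    validating event recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
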