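Package: genload
Title: Genetic Load, Purging Dynamics, and Runs of Homozygosity at Desk Scale
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolution of the deleterious mutation
    burden in declining populations. Provides a deterministic
    Wright-Fisher transition-matrix engine that predicts the expected
    number of segregating and fixed derived deleterious alleles per
    diploid genome under mutation-selection-drift equilibrium followed
    by stepwise population-size reductions; a stochastic forward
    Wright-Fisher simulator used both as an independent oracle for the
    matrix engine and as the genotype source for synthetic cohorts; a
    synthetic-data generator that emits fully specified diploid cohorts
    (genotypes, variant effect classes, outgroup alleles, implanted
    autozygous tracts, missingness) with recorded ground truth; and an
    empirical genetic-load pipeline covering codon degeneracy classes,
    windowed nucleotide diversity, individual heterozygosity, runs of
    homozygosity and F_ROH, outgroup-parsimony polarization of derived
    alleles, and zygosity- and ROH-stratified normalized burden ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    jsonlite,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    seqinr,
    withr
Config/testthat/edition: 3
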