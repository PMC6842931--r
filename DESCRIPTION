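Package: wssgwas
Title: Weighted Single-Step Genome-Wide Association for Repeated-Record Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-step genomic BLUP (ssGBLUP) on a repeatability animal
    model that combines genotyped and ungenotyped animals through the H
    relationship matrix, with backsolving of genomic breeding values into
    SNP effects, iterative SNP reweighting (WssGWAS), and partitioning of
    additive genetic variance into sliding windows of adjacent SNPs.
    Includes pedigree, genotype and repeated-phenotype simulators (gene
    dropping down a multi-generation pedigree) so the whole pipeline is
    testable without external data, plus readers, SNP quality control,
    window ranking, cross-trait overlap detection and Manhattan-style
    plotting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
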