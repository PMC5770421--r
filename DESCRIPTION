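Package: chromexch
Title: Spike-In Calibrated Chromatin Dynamics: Histone Exchange, Metagene
    Profiles, and ATAC Accessibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis layer for quantitative chromatin dynamics in budding
    yeast: spike-in calibrated ChIP-seq comparison between genotypes
    (enrichment ratio E^IP and the mutant-versus-wild-type scale factor N),
    replication-independent histone exchange scoring from Flag/Myc tagged
    histone ChIP (log2 Flag/Myc), gene-length stratified gene-body
    statistics (RPKM, center-of-transcribed-region windows, rank-based
    group comparison), TSS/TES anchored metagene matrices with beyond-TES
    masking, and ATAC-seq accessibility classification from subnucleosomal
    (<100 bp) fragments. Includes a deterministic synthetic fragment
    generator with recorded ground truth so every stage is testable
    without sequencing data, and recipe functions reproducing each
    figure-level analysis end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang (>= 1.0.0),
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
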