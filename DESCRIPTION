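Package: criollo
Title: Population Genomics and Isotope Traits for Bean Diversity Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for SNP-array diversity panels of common
    bean (Phaseolus vulgaris) contrasting landrace and participatory-bred
    subpopulations. Computes windowed nucleotide diversity and Tajima's D,
    Weir-Cockerham weighted F_ST with outlier-window extraction, diversity-
    ratio region calling, percent nitrogen derived from the atmosphere
    (15N natural abundance) and carbon isotope discrimination (water use
    efficiency), trait correlations and genotype-by-trait biplots, and
    panel structure summaries (distances, neighbor-joining with bootstrap,
    PCA). Includes a synthetic SNP-panel and isotope-phenotype generator
    with full ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    vcfR
Suggests:
    BiocGenerics,
    GenomeInfoDb,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
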