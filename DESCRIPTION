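Package: tfreloc
Title: Integrative ChIP-Seq and RNA-Seq Analysis of Transcription-Factor
    Complex Relocation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how an inducible transcription factor
    redistributes pre-bound factor complexes across regulatory sites,
    integrating ChIP-seq binding with RNA-seq expression responses.
    Provides pairwise peak comparison with fold-difference specificity
    classes, anchor-centred signal and motif-density matrices sharing a
    fixed ranked row order, three-set peak-overlap grouping with motif and
    expression annotation, 0/1/2 expression-response coding into eight
    groups, scaled gene-body metagene profiles, and a synthetic-data
    generator that embeds a known relocation scenario so every stage can
    be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    methods,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
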