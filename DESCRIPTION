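Package: cnvrgwas
Title: Copy Number Variation Region Construction and Mixed-Model
    Genome-Wide Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds copy number variation regions (CNVRs) from per-sample
    structural-variant calls, codes them as three-state genotypes
    (gain/normal/loss), constructs a CNV-derived genomic relationship
    matrix, and tests each region for association with quantitative traits
    under a mixed linear model fitted by restricted maximum likelihood with
    a one-decomposition (EMMAX-style) per-marker generalized least squares
    test. Includes landscape summaries (per-chromosome tables, type and
    size distributions, genome tracks), proximal-gene annotation within a
    flanking window, a seeded simulator of CNV landscapes and phenotypes
    with known heritability, and an end-to-end pipeline with a thin
    command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    vcfR,
    ape,
    IRanges,
    GenomicRanges,
    S4Vectors,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
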