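Package: retroepi
Title: Transposable-Element-Centric Epigenomics of TET-Regulated
    Retrotransposons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analyses of TET-family dioxygenase activity at transposable
    elements (TEs) in embryonic stem cells: permutation enrichment of
    ChIP-seq peaks over repeat classes against length-matched random
    interval nulls (optionally restricted to uniquely mappable regions),
    unique versus inclusive multi-mapping read assignment, anchor- and
    consensus-element meta-profiles (e.g. LINE-1 5' UTR coverage),
    5mC/5hmC estimation from bisulfite, oxidative-bisulfite and
    TET-assisted-bisulfite cytosine reports, family-age binding
    summaries, repeat-class expression pooling with median-of-ratios
    normalisation, and promoter-interaction linking of TE copies to
    genes.  A seeded synthetic-data generator emulates every input so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    DESeq2,
    Rsamtools,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
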