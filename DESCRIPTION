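Package: ctxlife
Title: Context-Dependent Quantitative Genetics of Life Span
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-genetic analysis of life span and its
    micro-environmental variance in replicated inbred-line panels reared in
    multiple environments, in the style of the Drosophila melanogaster
    Genetic Reference Panel (DGRP).  Provides REML variance-component
    estimation with broad-sense heritability and cross-sex / cross-environment
    genetic correlations, decomposition of interaction variance into
    rank-order and genetic-scale change, Brown-Forsythe and Cochran's C tests
    of within-line variance heterogeneity, line-mean genome-wide association
    scans with sex- and temperature-contrast phenotypes, pooled-sequencing
    extreme-QTL (xQTL) allele-frequency Z tests with cross-context contrasts,
    gene-length-corrected Gene Ontology enrichment by weighted permutation,
    and a synthetic-data generator that emulates both the replicated panel
    and an outbred advanced-intercross xQTL experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    Matrix,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    vcfR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
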