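Package: sagetag
Title: 5'-SAGE Ditag Processing, TSS Annotation and Digital Expression Profiling
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for 5'-Serial Analysis of Gene Expression
    (5'-SAGE) libraries sequenced as ~100 bp ditags: quality filtering and
    ditag splitting into 15-20 bp 5' tags, exact-match genome mapping with
    multiplicity classification, tag classification against gene models
    (5'-UTR/CDS/3'-UTR, sense/antisense) with per-gene transcription start
    site catalogues, tags-per-100,000 expression quantification with
    pairwise Fisher exact differential-expression calls, hypergeometric
    protein-domain enrichment, lineage-specificity classification from
    tabular homology reports, and cross-platform correlation against
    microarray and real-time RT-PCR log2 ratios. A synthetic-data module
    generates toy genomes, gene models and two-stage ditag read sets with
    known ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    jsonlite,
    yaml,
    withr,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
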