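Package: insetr
Title: Analysis of Lentiviral Insertional Mutagenesis Fitness Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical pipeline for insertional mutagenesis fitness screens
    based on lentiviral long terminal repeat (LTR) junction sequencing. Turns
    LTR-tagged paired-end reads into per-sample insertion-site tables, calls
    single insertions affecting cellular fitness (IACFs) by replicated paired
    testing on log-transformed normalized depths, calls enriched/depleted
    insertion clusters with a SICER-style island model and forms consensus
    clusters (CACFs) shared by replicates, assigns calls to genomic elements
    with a hierarchical one-category rule, computes enrichment odds ratios and
    conservation statistics, and validates candidate transcription start sites
    against CAGE tag atlases with a composition-matched shuffle null. Includes
    a synthetic-screen generator with planted fitness effects so the whole
    pipeline is testable without external data.
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
    jsonlite,
    methods,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
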