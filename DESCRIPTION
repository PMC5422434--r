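Package: linckit
Title: Identification and Evolutionary Profiling of Long Intergenic
    Non-Coding RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A two-stage pipeline for long intergenic non-coding RNA
    (lincRNA) analysis. The identification stage partitions assembled
    transcripts (GTF) into lincRNA, sense/antisense gene-overlapping, and
    transposable-element-derived classes using length, open reading frame,
    protein-similarity, and genomic-overlap filters. The conservation stage
    traces each lincRNA across a ranked panel of genomes by reciprocal
    top-hit homology search with a built-in k-mer seeded local aligner and
    Karlin-Altschul significance, builds per-query homolog families,
    aligns them, infers gene trees, and reconciles them against a species
    tree to call duplication and loss events. A seeded synthetic-data
    generator plants ground-truth genomes, annotations and homologs so
    the whole pipeline is testable without external databases.
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
    BiocGenerics,
    rtracklayer,
    ape,
    phangorn,
    jsonlite,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
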