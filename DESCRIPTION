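Package: underrep
Title: Comparative Genomics of Underreplicated Genomic Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Characterizes the gene content and molecular evolution of
    underreplicated regions (URs) of the Drosophila melanogaster genome:
    assignment of gene models to regions by fractional span coverage,
    selection of matched adjacent-gene controls, enrichment tests for
    conserved elements with length-proportional expected counts,
    Pamilo-Bianchi-Li synonymous and nonsynonymous distances on
    concatenated codon alignments, protein-length and replication-timing
    comparisons, and a seeded synthetic-genome generator that plants
    known ground truth for end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    methods,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    Biostrings,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
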