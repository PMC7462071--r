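Package: isopath
Title: Consensus-Seeded Genome-Guided Transcriptome Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-guided transcript assembly from spliced paired-end
    RNA-seq alignments. Builds a weighted splicing graph per gene locus,
    extracts reliable subpaths from paired-end reads and from the transcript
    sets of several upstream assemblers (merged in a colored graph), and
    recovers transcripts as a path cover of the weighted line graph by a
    seeded greedy path-extension search. Includes a deterministic synthetic
    data generator (toy genes, spliced read pairs, mock assembler GTFs) so
    the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    Biostrings,
    pracma,
    stats,
    utils
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
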