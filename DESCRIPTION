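Package: junctionprimer
Title: Transcript-Specific RT-qPCR Primer Design at Exon-Exon Junctions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs transcript-specific RT-qPCR primer pairs anchored on
    exon-exon junctions. Builds spliced transcript models from a genome FASTA
    plus GTF/GFF annotation (or custom FASTA/GenBank transcripts), selects
    junctions that discriminate a user-chosen set of isoforms, masks common
    variants so primers avoid polymorphic positions, enumerates
    junction-spanning or junction-flanking primer pairs under nearest-neighbor
    melting-temperature and structural constraints, and screens specificity by
    exhaustive in-silico PCR against spliced-transcript and genomic sequence
    databases in two sequential rounds. Includes a seeded synthetic-locus
    generator with ground truth for end-to-end testing and a command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    vcfR,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    stringr,
    readr,
    jsonlite,
    ggplot2,
    generics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
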