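Package: wrkyfam
Title: Identification and Comparative Analysis of WRKY Transcription Factor Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for genome-scale analysis of the WRKY
    transcription factor family. Detects WRKY domains by scanning for the
    conserved heptapeptide (WRKYGQK and variants) followed by a C2H2 or C2HC
    zinc finger with canonical spacer lengths, classifies proteins into
    groups I/II/III by domain architecture and into subgroups IIa-IIe by
    reference-guided neighbor-joining placement with bootstrap support,
    computes physicochemical descriptors (isoelectric point, GRAVY,
    instability and aliphatic indices), scans promoters for cis-regulatory
    elements, calls homolog groups by Markov clustering of pairwise
    similarity with typed ortholog/paralog/coortholog pair tallies, and
    quantifies expression by RPKM, qPCR 2^-ddCt fold changes and Pearson
    co-expression networks. Ships transcriptions of a published carrot
    (Daucus carota) WRKY family table and cross-species homolog pair table
    as worked-example fixtures, plus seeded synthetic-data generators that
    provide ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn
Config/testthat/edition: 3
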