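Package: ltrscout
Title: Discovery of Non-Reference ERV-LTR Insertions from Paired-End Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects non-reference endogenous retrovirus (ERV) long terminal
    repeat (LTR) insertion loci from coordinate-sorted paired-end alignments.
    Read pairs are classified into proper, discordant, split, singleton and
    unmapped classes; non-proper evidence is matched against an LTR query
    library, clustered into breakpoint calls, filtered by support and
    confidence level, and authenticated by automatic target-site-duplication
    (TSD) detection. Junction-spanning reads are assembled into local contigs
    by greedy overlap-layout-consensus, the inserted sequence is deduced from
    TSD-delimited junctions, and classified against the library by local
    alignment with an e-value-like statistic. Downstream layers build
    cross-individual presence/absence locus matrices, Venn partitions,
    binary-distance clustering trees, gene-overlap annotation with
    hypergeometric GO enrichment, and per-locus LTR analysis (progressive
    alignment, substitution counting, U3/R/U5 segmentation, EAV mosaic
    pattern typing, K2P distances and neighbor-joining trees). A cohort
    simulator generates reference genomes, LTR libraries, donor genomes with
    germline insertions on a species tree, paired-end reads and truth tables
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
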