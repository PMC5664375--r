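Package: ifcr
Title: Internal Fusion Clone Ratio Estimation from RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the relative clonal size of fusion-bearing tumour
    subpopulations from RNA-seq alone. Counts breakpoint-spanning reads at
    the genomic junctions of a fusion's two parent genes (overlapping
    reads) and, optionally, against a constructed chimeric contig (fusion
    reads), then forms the internal Fusion Clone Ratio (iFCR) in its
    average, maximum and minimum variants. Includes single-cell
    aggregation with a cell-count cross-check, recurrence-based cohort
    comparisons, RPKM expression summaries, and a seeded clone-mixture
    read simulator that writes SAM/FASTA/GTF fixtures with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
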