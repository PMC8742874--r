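Package: rbmotif
Title: RNA-Binding Protein Motif Scanning, Annotation and Co-Occurrence
    Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for locating RNA-binding protein motifs
    (position weight matrix log-odds or IUPAC consensus) in gene sequences,
    assigning motif instances to genes and gene features (intron, exon, CDS,
    5'-UTR, 3'-UTR) with transcribed-strand filtering, and computing the
    statistics used to characterise motif landscapes in a transcriptome:
    per-category motif-presence percentages with a random-gene-set Monte
    Carlo expectation, two-motif co-occurrence fractions, distance from each
    motif instance to the nearest instance of a second motif with a
    uniform-placement-in-exons null distribution, splice-junction usage
    percentages from STAR SJ.out.tab counts, and gel-densitometry
    quantification (percent of signal and normalised fold change). Includes
    a seeded synthetic-data generator (annotated mini-genomes, planted
    motifs with controlled rates and proximities, junction tables and band
    tables with known truth) so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    withr,
    stats,
    utils,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    IRanges,
    jsonlite,
    optparse
Config/testthat/edition: 3
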