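Package: regulonscan
Title: Promoter Motif Discovery and Regulon Filtering for Bacterial
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Infers candidate transcription-factor binding motifs from
    bacterial differential-expression tables. Extracts 550-bp promoter
    windows (500 bp upstream, 50 bp downstream of the start codon) for
    induced genes, discovers over-represented motifs with an
    any-number-of-repetitions expectation-maximisation model, scans the
    promoter windows of all genes with exact position-weight-matrix
    p-values and Benjamini-Hochberg q-values, and filters motifs with two
    regulator-likeness criteria (at most 1000 genome-wide sites; more
    than 10 percent of sites upstream of first genes of induced operons).
    A phylogenetic-footprinting variant pools promoter regions of ranked
    homologs and re-estimates motifs from their genomic sites. Includes a
    synthetic-data generator that plants palindromic regulon motifs into
    simulated genomes so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
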