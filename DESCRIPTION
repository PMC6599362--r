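Package: plantmir
Title: Plant MicroRNA Locus Discovery from Small RNA-Seq Read Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies microRNA (miRNA) genes in plant genomes from small RNA
    sequencing alignments. Read-enriched peaks are paired with nearby
    complementary windows, folded into locally stable stem-loop precursors
    with the ViennaRNA programs, and scored on six explicit criteria
    (thermodynamic stability via the MFE index, read support, guide miRNA
    existence, processing precision, passenger strand expression and duplex
    geometry) yielding a 0-6 quality score. Includes annotation of
    conservation against known mature miRNAs and of genomic duplications,
    text read-cloud reports, CSV/GFF/dot-bracket/ORG exports, and a synthetic
    fixture generator that plants hairpin loci with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    Rsamtools,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
SystemRequirements: ViennaRNA (RNALfold, RNAfold, RNAeval on the PATH)
Config/testthat/edition: 3
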