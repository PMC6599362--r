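# Read prefiltering: annotation masking, multi-mapper removal and
# segregation of reads that fall in already-annotated miRNA precursors.
# Filter priority when a read qualifies for several bins:
# known miRNA > annotation mask > multimapper.

#' Mask reads overlapping annotated features
#'
#' A read is masked when it overlaps any feature by at least 1 bp,
#' irrespective of strand. Typical masking sets are CDS, tRNA, rRNA and
#' snoRNA annotations, which absorb degradation products that would
#' otherwise seed spurious hairpin candidates.
#'
#' @param reads tibble of read alignments.
#' @param features tibble of annotation features ([read_gff()]).
#' @return list with tibbles `retained` and `masked`, both in genomic order.
#' @export
mask_by_annotation <- function(reads, features) {
  reads <- validate_reads(reads)
  if (!nrow(reads) || is.null(features) || !nrow(features)) {
    return(list(retained = order_reads(reads), masked = empty_reads()))
  }
  hits <- GenomicRanges::findOverlaps(
    reads_to_granges(reads), features_to_granges(features),
    minoverlap = 1L, ignore.strand = TRUE
  )
  masked_idx <- unique(S4Vectors::queryHits(hits))
  list(
    retained = order_reads(reads[setdiff(seq_len(nrow(reads)), masked_idx), ]),
    masked = order_reads(reads[masked_idx, ])
  )
}

#' Remove promiscuous multi-mapping reads
#'
#' Reads whose sequence maps to more than `max_hits` loci genome-wide are
#' removed; reads at exactly `max_hits` loci are kept. This guards against
#' transposable-element-derived siRNAs masquerading as miRNA loci.
#'
#' @param reads tibble of read alignments with `n_hits` populated.
#' @param max_hits maximum tolerated number of genomic loci (default 5).
#' @return list with tibbles `retained` and `removed`.
#' @export
filter_multimapped <- function(reads, max_hits = 5) {
  if (max_hits < 1) abort("max_hits must be >= 1")
  reads <- validate_reads(reads, require_hits = TRUE)
  keep <- reads$n_hits <= max_hits
  list(retained = order_reads(reads[keep, ]),
       removed = order_reads(reads[!keep, ]))
}

#' Assign reads to known miRNA precursors
#'
#' Reads overlapping an annotated precursor by at least 1 bp on the same
#' strand are attributed to that precursor and excluded from de novo
#' discovery; the report gives the total expression of each known locus.
#'
#' @param reads tibble of read alignments.
#' @param known_features tibble of known precursor coordinates (may be
#'   empty or `NULL`).
#' @return list with `report` (tibble: one row per known precursor with
#'   `n_reads` total copies and `n_unique` distinct reads) and `remaining`
#'   (reads left for de novo discovery).
#' @export
detect_known_mirnas <- function(reads, known_features) {
  reads <- validate_reads(reads)
  if (!nrow(reads) || is.null(known_features) || !nrow(known_features)) {
    return(list(
      report = tibble(id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      n_reads = integer(), n_unique = integer()),
      remaining = order_reads(reads)
    ))
  }
  hits <- GenomicRanges::findOverlaps(
    reads_to_granges(reads), features_to_granges(known_features),
    minoverlap = 1L, ignore.strand = FALSE
  )
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  report <- tibble(
    id = if (!is.null(known_features$id)) known_features$id else
      sprintf("%s__%d-%d_%s", known_features$chrom, known_features$start,
              known_features$end, known_features$strand),
    chrom = known_features$chrom, start = known_features$start,
    end = known_features$end, strand = known_features$strand,
    n_reads = vapply(seq_len(nrow(known_features)), function(i) {
      sum(reads$count[q[s == i]])
    }, numeric(1)) |> as.integer(),
    n_unique = vapply(seq_len(nrow(known_features)), function(i) {
      length(unique(q[s == i]))
    }, integer(1))
  )
  list(report = report,
       remaining = order_reads(reads[setdiff(seq_len(nrow(reads)),
                                             unique(q)), ]))
}

#' Run the full prefilter stage
#'
#' Applies, in priority order, known-miRNA segregation, annotation masking
#' and multi-mapper removal, and tallies a partition report in which every
#' input read record lands in exactly one bin.
#'
#' @param reads tibble of read alignments.
#' @param mask_features annotation features to mask (or `NULL`).
#' @param known_features known precursor coordinates (or `NULL`).
#' @param max_hits multi-mapping threshold (default 5).
#' @param mask_annotations logical; disable masking entirely.
#' @return list with `retained` reads, `report` (one-row tibble with
#'   `n_input`, `n_known_mirna`, `n_masked`, `n_multimap_removed`,
#'   `n_retained`) and `known_report`.
#' @export
prefilter_reads <- function(reads, mask_features = NULL,
                            known_features = NULL, max_hits = 5,
                            mask_annotations = TRUE) {
  reads <- validate_reads(reads)
  n_input <- nrow(reads)
  known <- detect_known_mirnas(reads, known_features)
  n_known <- n_input - nrow(known$remaining)
  if (mask_annotations) {
    masked <- mask_by_annotation(known$remaining, mask_features)
  } else {
    masked <- list(retained = known$remaining, masked = empty_reads())
  }
  multi <- filter_multimapped(masked$retained, max_hits = max_hits)
  report <- tibble(
    n_input = n_input,
    n_known_mirna = n_known,
    n_masked = nrow(masked$masked),
    n_multimap_removed = nrow(multi$removed),
    n_retained = nrow(multi$retained)
  )
  stopifnot(report$n_input == report$n_known_mirna + report$n_masked +
              report$n_multimap_removed + report$n_retained)
  list(retained = multi$retained, report = report,
       known_report = known$report)
}
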