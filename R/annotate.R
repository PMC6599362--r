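# Conservation and duplication annotation of predictions.

#' Align known mature miRNAs to a candidate precursor
#'
#' Edit-distance alignment (mismatches + indels) of every database mature
#' sequence against the precursor, keeping hits with at most `max_edits`
#' total edits and no two adjacent indel columns. Hits overlapping the
#' guide interval are flagged: conservation that coincides with the
#' expressed miRNA is the strongest evidence.
#'
#' @param candidate_seq precursor RNA string.
#' @param db tibble with columns `id` and `seq` ([read_mature_db()]).
#' @param max_edits maximum mismatches + indels (default 3).
#' @param guide_interval optional 0-based half-open guide interval in the
#'   precursor, used to set `overlaps_guide`.
#' @return tibble of hits: `db_id`, `db_seq`, `local_start`, `local_end`
#'   (0-based half-open), `n_edits`, `overlaps_guide`.
#' @export
align_to_known_matures <- function(candidate_seq, db, max_edits = 3,
                                   guide_interval = NULL) {
  candidate_seq <- as_rna(candidate_seq)
  empty <- tibble(db_id = character(), db_seq = character(),
                  local_start = integer(), local_end = integer(),
                  n_edits = integer(), overlaps_guide = logical())
  if (is.null(db) || !nrow(db)) return(empty)
  hits <- purrr::map(seq_len(nrow(db)), function(k) {
    m <- .edit_hits_cpp(as_rna(db$seq[k]), candidate_seq,
                        as.integer(max_edits))
    if (!nrow(m)) return(NULL)
    h <- as_tibble(m) |>
      arrange(.data$edits, .data$start) |>
      # one best hit per region: greedy removal of overlapping hits
      (\(x) {
        keep <- logical(nrow(x))
        taken_lo <- integer()
        taken_hi <- integer()
        for (i in seq_len(nrow(x))) {
          ov <- any(x$start[i] < taken_hi & x$end[i] > taken_lo)
          if (!ov) {
            keep[i] <- TRUE
            taken_lo <- c(taken_lo, x$start[i])
            taken_hi <- c(taken_hi, x$end[i])
          }
        }
        x[keep, ]
      })()
    tibble(db_id = db$id[k], db_seq = as_rna(db$seq[k]),
           local_start = h$start, local_end = h$end,
           n_edits = h$edits)
  })
  hits <- bind_rows(purrr::compact(hits))
  if (!nrow(hits)) return(empty)
  hits$overlaps_guide <- if (is.null(guide_interval)) FALSE else
    hits$local_start < guide_interval[2] & hits$local_end > guide_interval[1]
  arrange(hits, .data$local_start, .data$db_id)
}

#' Genomic duplication check of a guide sequence
#'
#' Exact-match scan of the guide and its reverse complement over the whole
#' genome. Multi-copy miRNAs are reported together with whether any other
#' occurrence falls inside another prediction.
#'
#' @param guide_seq guide RNA string.
#' @param genome [Biostrings::DNAStringSet].
#' @param predictions optional predictions tibble; used to flag
#'   occurrences inside other predicted precursors.
#' @param self_interval optional `list(chrom =, start =, end =)` of the
#'   prediction the guide belongs to, excluded from the overlap flag.
#' @return one-row tibble: `n_genomic_occurrences`, `other_loci` (list of
#'   a tibble of occurrence intervals), `overlaps_other_prediction`.
#' @export
duplication_check <- function(guide_seq, genome, predictions = NULL,
                              self_interval = NULL) {
  pat <- Biostrings::DNAString(as_dna(guide_seq))
  occ <- purrr::map(names(genome), function(chrom) {
    fwd <- Biostrings::matchPattern(pat, genome[[chrom]])
    rev <- Biostrings::matchPattern(Biostrings::reverseComplement(pat),
                                    genome[[chrom]])
    bind_rows(
      tibble(chrom = chrom,
             start = Biostrings::start(fwd) - 1L,
             end = Biostrings::end(fwd), strand = "+"),
      tibble(chrom = chrom,
             start = Biostrings::start(rev) - 1L,
             end = Biostrings::end(rev), strand = "-")
    )
  }) |> bind_rows()
  other <- occ
  if (!is.null(self_interval)) {
    # occurrences inside the prediction's own precursor (including the
    # guide's complement on the star arm) are the locus itself, not a
    # duplication
    other <- filter(occ, !(.data$chrom == self_interval$chrom &
                             .data$start < self_interval$end &
                             .data$end > self_interval$start))
    n <- 1L + nrow(other)
  } else {
    n <- max(1L, nrow(occ))
  }
  overlaps <- FALSE
  if (!is.null(predictions) && nrow(predictions) && nrow(other)) {
    preds <- predictions
    if (!is.null(self_interval)) {
      preds <- filter(preds, !(.data$chrom == self_interval$chrom &
                                 .data$start < self_interval$end &
                                 .data$end > self_interval$start))
    }
    if (nrow(preds)) {
      overlaps <- any(purrr::map_lgl(seq_len(nrow(other)), function(i) {
        any(preds$chrom == other$chrom[i] &
              preds$start < other$end[i] & preds$end > other$start[i])
      }))
    }
  }
  tibble(n_genomic_occurrences = as.integer(n),
         other_loci = list(other),
         overlaps_other_prediction = overlaps)
}

#' Guide weight
#'
#' Copy count of the guide miRNA normalized by the number of occurrences
#' of its sequence in the genome; a multi-mapping miRNA shares its read
#' support across loci.
#'
#' @param guide_count guide copy count.
#' @param n_genomic_occurrences occurrences of the guide sequence in the
#'   genome (>= 1).
#' @return numeric weight.
#' @export
compute_weight <- function(guide_count, n_genomic_occurrences) {
  if (any(n_genomic_occurrences < 1)) {
    abort("n_genomic_occurrences must be >= 1")
  }
  guide_count / n_genomic_occurrences
}
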