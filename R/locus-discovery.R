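# Peak calling on read alignments and duplex-partner search. A candidate
# precursor locus is a read-enriched window plus a nearby window it can
# base-pair with, which is the read-level signature of a stem-loop.

cluster_reads_one <- function(reads, cluster_gap) {
  reads <- arrange(reads, .data$start, .data$end)
  gap_break <- c(TRUE, reads$start[-1] - cummax(reads$end)[-nrow(reads)] >
                   cluster_gap)
  reads$cluster <- cumsum(gap_break)
  reads
}

cluster_max_depth <- function(starts, ends, counts) {
  lo <- min(starts)
  cov <- numeric(max(ends) - lo + 1L)
  for (i in seq_along(starts)) {
    a <- starts[i] - lo + 1L
    b <- ends[i] - lo
    cov[a:b] <- cov[a:b] + counts[i]
  }
  as.integer(max(cov))
}

# Optimal 1-D 2-means split (sorted data, single split point minimizing
# within-group sum of squares). Returns a logical "high group" mask.
split_two_means <- function(x) {
  if (length(unique(x)) < 2) return(rep(TRUE, length(x)))
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  wss <- vapply(seq_len(n - 1), function(k) {
    lo <- xs[1:k]
    hi <- xs[(k + 1):n]
    sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
  }, numeric(1))
  k <- which.min(wss)
  thresh <- xs[k + 1]
  x >= thresh
}

#' Call read-enriched peaks
#'
#' Reads separated by at most `cluster_gap` nt (per chromosome and strand)
#' are merged into clusters; cluster log10 total copy counts are then split
#' by an exact 1-D 2-means into background and signal groups. Clusters in
#' the signal group, plus any cluster with at least `peak_floor` copies,
#' become peaks. When all clusters have equal counts the split is
#' undefined and every cluster is kept.
#'
#' @param reads tibble of (prefiltered) read alignments.
#' @param cluster_gap maximum nt gap joining reads into one cluster.
#' @param peak_floor absolute copy-count rescue threshold.
#' @return tibble of peaks: `chrom`, `strand`, `start`, `end`,
#'   `total_count`, `max_depth`, `n_reads`.
#' @export
call_peaks <- function(reads, cluster_gap = 30, peak_floor = 10) {
  empty <- tibble(chrom = character(), strand = character(),
                  start = integer(), end = integer(),
                  total_count = integer(), max_depth = integer(),
                  n_reads = integer())
  if (!nrow(reads)) return(empty)
  reads <- validate_reads(reads)
  clusters <- reads |>
    group_by(.data$chrom, .data$strand) |>
    dplyr::group_modify(~cluster_reads_one(.x, cluster_gap)) |>
    ungroup() |>
    group_by(.data$chrom, .data$strand, .data$cluster) |>
    summarise(
      start = min(.data$start), end = max(.data$end),
      total_count = as.integer(sum(.data$count)),
      max_depth = cluster_max_depth(.data$start, .data$end, .data$count),
      n_reads = n(), .groups = "drop"
    ) |>
    filter(.data$end - .data$start >= 18L)
  if (!nrow(clusters)) return(empty)
  high <- split_two_means(log10(clusters$total_count))
  clusters |>
    filter(high | .data$total_count >= peak_floor) |>
    select(-"cluster") |>
    arrange(.data$chrom, .data$start, .data$strand)
}

#' Best base-pairing between two RNA windows
#'
#' Scores how well sequence `a` can form a stem with sequence `b` when both
#' lie on the same transcript: `a` is aligned against the reverse of `b`
#' and the number of positions forming C-G, A-U or G-U pairs is maximized
#' over all alignments with free end gaps and at most `max_bulges` internal
#' bulges of at most `bulge_len` nt each.
#'
#' @param a,b RNA strings.
#' @param max_bulges maximum number of internal bulges.
#' @param bulge_len maximum length of each bulge (nt).
#' @return integer count of paired positions in the best alignment.
#' @export
pairing_matrix <- function(a, b, max_bulges = 2, bulge_len = 2) {
  a <- as_rna(a)
  b <- as_rna(b)
  check_rna(c(a, b))
  if (!nzchar(a) || !nzchar(b)) abort("sequences must be non-empty")
  .pairing_score_cpp(a, b, as.integer(max_bulges), as.integer(bulge_len))
}

#' Find a duplex partner window for a peak
#'
#' Slides windows of peak length within `max_distance` nt on either side of
#' the peak (clipped to the chromosome) and keeps the best-pairing window;
#' a candidate locus spanning peak and partner is returned when at least
#' `min_paired` positions pair, otherwise `NULL`. Windows nearly identical
#' to the peak itself are excluded.
#'
#' @param peak one-row tibble from [call_peaks()].
#' @param genome [Biostrings::DNAStringSet].
#' @param max_distance search radius in nt (default 350).
#' @param min_paired minimum paired positions to accept a partner.
#' @param max_bulges,bulge_len bulge tolerance (see [pairing_matrix()]).
#' @return one-row candidate tibble (`chrom`, `strand`, `start`, `end`,
#'   `peak_start`, `peak_end`, `total_count`, `max_depth`,
#'   `partner_offset`, `pairing_score`) or `NULL`.
#' @export
find_duplex_partner <- function(peak, genome, max_distance = 350,
                                min_paired = 14, max_bulges = 2,
                                bulge_len = 2) {
  stopifnot(nrow(peak) == 1)
  chrom_len <- Biostrings::width(genome[peak$chrom])
  ra <- max(0L, peak$start - as.integer(max_distance))
  rb <- min(chrom_len, peak$end + as.integer(max_distance))
  region <- extract_genome(genome, peak$chrom, ra, rb, peak$strand)
  L <- peak$end - peak$start
  peak_local <- if (peak$strand == "+") peak$start - ra else rb - peak$end
  peak_seq <- substr(region, peak_local + 1L, peak_local + L)
  hit <- .partner_scan_cpp(peak_seq, region, as.integer(peak_local),
                           as.integer(max_bulges), as.integer(bulge_len),
                           0.9)
  if (hit$start < 0 || hit$score < min_paired) return(NULL)
  w <- hit$start
  # signed gap between peak and partner on the expressed 5'->3' axis:
  # positive when the partner starts downstream of the peak end
  offset <- if (w >= peak_local + L) {
    w - (peak_local + L)
  } else if (w + L <= peak_local) {
    (w + L) - peak_local
  } else {
    w - peak_local
  }
  win_genomic <- if (peak$strand == "+") {
    c(ra + w, ra + w + L)
  } else {
    c(rb - w - L, rb - w)
  }
  tibble(
    chrom = peak$chrom, strand = peak$strand,
    start = min(peak$start, win_genomic[1]),
    end = max(peak$end, win_genomic[2]),
    peak_start = peak$start, peak_end = peak$end,
    total_count = peak$total_count, max_depth = peak$max_depth,
    partner_offset = as.integer(offset),
    pairing_score = as.integer(hit$score)
  )
}

#' Discover candidate precursor loci
#'
#' Runs [call_peaks()] and [find_duplex_partner()] over all peaks.
#'
#' @inheritParams call_peaks
#' @inheritParams find_duplex_partner
#' @return tibble of candidate loci (possibly empty).
#' @export
discover_loci <- function(reads, genome, cluster_gap = 30, peak_floor = 10,
                          max_distance = 350, min_paired = 14,
                          max_bulges = 2, bulge_len = 2) {
  peaks <- call_peaks(reads, cluster_gap = cluster_gap,
                      peak_floor = peak_floor)
  cands <- purrr::map(seq_len(nrow(peaks)), function(i) {
    find_duplex_partner(peaks[i, ], genome, max_distance = max_distance,
                        min_paired = min_paired, max_bulges = max_bulges,
                        bulge_len = bulge_len)
  })
  cands <- purrr::compact(cands)
  if (!length(cands)) {
    return(tibble(chrom = character(), strand = character(),
                  start = integer(), end = integer(),
                  peak_start = integer(), peak_end = integer(),
                  total_count = integer(), max_depth = integer(),
                  partner_offset = integer(), pairing_score = integer()))
  }
  bind_rows(cands)
}
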