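# Six-criterion quality scoring of a hairpin and its read cloud.
# Criteria: (1) MFEI < -0.8; (2) read support (>=10 per arm or >=100
# total); (3) a guide miRNA exists (most common read >= 1/3 of copies);
# (4) >= 75% of read starts fall in [-3,+3] of the guide start or [-5,+5]
# of the pairing position on the other arm; (5) at least one read in the
# star window; (6) stable duplex geometry (2-nt 3' overhangs, extensive
# pairing). Criteria 4-6 require a defined guide; the score is the count
# of satisfied criteria, so loci without a clear miRNA top out at 2 and
# loci without passenger evidence at 5.

#' Restrict reads to a hairpin locus
#'
#' Builds the read cloud of a precursor: reads on the same chromosome and
#' strand intersecting the hairpin interval, with precursor-local start
#' offsets on the expressed 5'->3' axis.
#'
#' @param hairpin one-row hairpin tibble ([fold_candidate()]).
#' @param reads tibble of read alignments.
#' @return list with elements `hairpin` and `reads` (reads gain
#'   `local_start`, `local_end` and `arm` columns).
#' @export
read_cloud_locus <- function(hairpin, reads) {
  stopifnot(nrow(hairpin) == 1)
  sel <- reads$chrom == hairpin$chrom & reads$strand == hairpin$strand &
    reads$start < hairpin$end & reads$end > hairpin$start
  cloud <- reads[sel, ]
  if (nrow(cloud)) {
    if (hairpin$strand == "+") {
      cloud$local_start <- cloud$start - hairpin$start
    } else {
      cloud$local_start <- hairpin$end - cloud$end
    }
    cloud$local_end <- cloud$local_start + (cloud$end - cloud$start)
    cloud$arm <- assign_arm(cloud$local_start, cloud$local_end,
                            hairpin$loop_start, hairpin$loop_end,
                            hairpin$length)
    cloud <- arrange(cloud, .data$local_start, desc(.data$count),
                     .data$sequence)
  } else {
    cloud$local_start <- integer()
    cloud$local_end <- integer()
    cloud$arm <- character()
  }
  list(hairpin = hairpin, reads = cloud)
}

# Majority-overlap arm assignment; reads mostly in the loop belong to
# neither arm ("none") but still count toward locus totals.
assign_arm <- function(local_start, local_end, loop_start, loop_end, len) {
  ov <- function(a, b) pmax(0, pmin(local_end, b) - pmax(local_start, a))
  ov5 <- ov(0L, loop_start)
  ovl <- ov(loop_start, loop_end)
  ov3 <- ov(loop_end, len)
  dplyr::case_when(
    ov5 > ovl & ov5 > ov3 ~ "5p",
    ov3 > ovl & ov3 > ov5 ~ "3p",
    .default = "none"
  )
}

#' Criterion 1: thermodynamic stability
#'
#' @param mfei MFE index of the precursor structure.
#' @param threshold strict upper bound (default -0.8).
#' @return logical.
#' @export
criterion1_stability <- function(mfei, threshold = -0.8) {
  !is.na(mfei) & mfei < threshold
}

#' Criterion 2: read support
#'
#' @param locus read-cloud locus ([read_cloud_locus()]).
#' @param min_arm_reads per-arm copy threshold (default 10).
#' @param min_total_reads total copy threshold (default 100).
#' @return logical.
#' @export
criterion2_reads <- function(locus, min_arm_reads = 10,
                             min_total_reads = 100) {
  r <- locus$reads
  total <- sum(r$count)
  c5 <- sum(r$count[r$arm == "5p"])
  c3 <- sum(r$count[r$arm == "3p"])
  (c5 >= min_arm_reads && c3 >= min_arm_reads) || total >= min_total_reads
}

#' Criterion 3: guide miRNA selection
#'
#' The most common unique read (by copy count, ties broken by 5'-most
#' start then lexicographic sequence) becomes the guide when its frequency
#' among all copies at the locus reaches `min_freq`.
#'
#' @param locus read-cloud locus.
#' @param min_freq minimum copy-count frequency (default 1/3).
#' @return one-row tibble (`sequence`, `local_start`, `length`, `count`,
#'   `freq`, `arm`) or `NULL` when no read qualifies.
#' @export
select_guide <- function(locus, min_freq = 1 / 3) {
  r <- locus$reads
  if (!nrow(r)) return(NULL)
  total <- sum(r$count)
  top <- r |>
    arrange(desc(.data$count), .data$local_start, .data$sequence) |>
    dplyr::slice(1)
  freq <- top$count / total
  if (freq < min_freq) return(NULL)
  tibble(sequence = top$sequence, local_start = top$local_start,
         length = nchar(top$sequence), count = top$count, freq = freq,
         arm = top$arm)
}

# Extrapolated 1-based pairing partner of 1-based position q, using the
# nearest paired position among `within` (pairing is anti-monotone along
# an arm, so the offset transfers with opposite sign).
partner_extrapolated <- function(pt, q, within) {
  within <- within[within >= 1 & within <= length(pt)]
  paired <- within[!is.na(pt[within])]
  if (!length(paired)) abort("no paired bases to map through")
  p <- paired[which.min(abs(paired - q))]
  pt[p] - (q - p)
}

#' Expected passenger (star) 5' start position
#'
#' Maps the guide through the structure's pair table to the opposite arm
#' and applies the canonical 2-nt 3' overhang left by Dicer-type cleavage:
#' the star 5' end pairs with the guide base two positions upstream of the
#' guide 3' end. Guide bases unpaired at the mapping point are handled by
#' linear extrapolation from the nearest paired base.
#'
#' @param structure precursor dot-bracket string.
#' @param guide_local_start 0-based guide start in the precursor.
#' @param guide_len guide length in nt.
#' @return 0-based expected star start position.
#' @export
expected_star_position <- function(structure, guide_local_start, guide_len) {
  pt <- pair_table(structure)
  part <- hairpin_partition(structure)
  g1 <- guide_local_start + 1L # 1-based guide start
  g2 <- guide_local_start + guide_len # 1-based guide end
  in_arm5 <- g1 <= part$arm5[2]
  in_arm3 <- g2 > part$loop[2]
  if (in_arm5 && in_arm3) abort("guide overlaps terminal loop")
  q <- g2 - 2L # guide base pairing with the star 5' end
  star1 <- partner_extrapolated(pt, q, g1:g2)
  max(0L, as.integer(star1) - 1L)
}

#' Criterion 4: processing precision
#'
#' @param locus read-cloud locus.
#' @param guide guide row from [select_guide()].
#' @param star_pos expected star start ([expected_star_position()]), or
#'   `NA` when unavailable.
#' @param frac minimum fraction of copies starting in the windows.
#' @param guide_window,star_window half-widths of the guide and star
#'   windows (defaults 3 and 5 nt).
#' @return logical.
#' @export
criterion4_precision <- function(locus, guide, star_pos = NA, frac = 0.75,
                                 guide_window = 3, star_window = 5) {
  r <- locus$reads
  total <- sum(r$count)
  if (total == 0) return(FALSE)
  in_guide <- abs(r$local_start - guide$local_start) <= guide_window
  in_star <- if (is.na(star_pos)) rep(FALSE, nrow(r)) else
    abs(r$local_start - star_pos) <= star_window
  sum(r$count[in_guide | in_star]) >= frac * total
}

#' Criterion 5: passenger strand expression
#'
#' @inheritParams criterion4_precision
#' @return logical: any read copy starts within the star window.
#' @export
criterion5_star_expressed <- function(locus, star_pos, star_window = 5) {
  if (is.na(star_pos)) return(FALSE)
  r <- locus$reads
  any(abs(r$local_start - star_pos) <= star_window & r$count >= 1)
}

#' Default duplex-geometry rule (criterion 6)
#'
#' Rule-based assessment of miRNA:miRNA* duplex stability: at least 75% of
#' guide bases paired, implied 3' overhangs of 2±1 nt at both duplex ends,
#' and no internal loop longer than 3 nt inside the duplex.
#'
#' @param hairpin one-row hairpin tibble.
#' @param guide guide row from [select_guide()].
#' @param min_paired_frac minimum fraction of paired guide bases.
#' @param overhang_tol accepted overhangs are `2 +/- overhang_tol`.
#' @param max_internal_loop largest tolerated internal loop (nt).
#' @return logical.
#' @export
duplex_rule_default <- function(hairpin, guide, min_paired_frac = 0.75,
                                overhang_tol = 1, max_internal_loop = 3) {
  pt <- pair_table(hairpin$structure)
  g1 <- guide$local_start + 1L
  g2 <- guide$local_start + guide$length
  if (g1 < 1 || g2 > length(pt)) return(FALSE)
  gpos <- g1:g2
  paired <- gpos[!is.na(pt[gpos])]
  if (length(paired) / guide$length < min_paired_frac) return(FALSE)
  star <- tryCatch(
    expected_star_position(hairpin$structure, guide$local_start,
                           guide$length),
    error = function(e) NA_integer_
  )
  if (is.na(star)) return(FALSE)
  s1 <- star + 1L
  s2 <- star + guide$length
  if (s2 > length(pt)) return(FALSE)
  # 3' overhangs: star 3' end past the partner of the guide 5' start, and
  # guide 3' end past the partner of the star 5' start
  oh_star <- s2 - partner_extrapolated(pt, g1, gpos)
  oh_guide <- g2 - partner_extrapolated(pt, s1, s1:s2)
  if (abs(oh_star - 2) > overhang_tol || abs(oh_guide - 2) > overhang_tol) {
    return(FALSE)
  }
  if (length(paired) >= 2) {
    gap_g <- diff(paired) - 1L
    gap_s <- abs(diff(pt[paired])) - 1L
    if (max(pmax(gap_g, gap_s)) > max_internal_loop) return(FALSE)
  }
  TRUE
}

#' Criterion 6: duplex stability
#'
#' Evaluates the miRNA:miRNA* duplex with a pluggable predicate; the
#' default is [duplex_rule_default()]. Any function of
#' `(hairpin, guide)` returning a logical can be substituted.
#'
#' @inheritParams duplex_rule_default
#' @param rule predicate function `(hairpin, guide) -> logical`.
#' @return logical.
#' @export
criterion6_duplex_stability <- function(hairpin, guide,
                                        rule = duplex_rule_default) {
  isTRUE(rule(hairpin, guide))
}

#' Compute the 0-6 quality score of a locus
#'
#' Evaluates all six criteria on a read-cloud locus. Criteria 4-6 are
#' forced false when no guide is defined, so loci without a clear miRNA
#' score at most 2, and loci without passenger-strand evidence at most 5.
#' Individual criteria can be replaced through `criterion_funs` (a named
#' list with any of `c1`..`c6`, each a function of
#' `(locus, guide, star_pos)`), which is how alternative duplex
#' classifiers plug in.
#'
#' @param locus read-cloud locus ([read_cloud_locus()]).
#' @param mfei_star_threshold criterion-1 threshold (default -0.8).
#' @param min_arm_reads,min_total_reads criterion-2 thresholds.
#' @param guide_min_freq criterion-3 frequency threshold (default 1/3).
#' @param precision_frac criterion-4 fraction (default 0.75).
#' @param guide_window,star_window criterion-4/5 window half-widths.
#' @param duplex_rule criterion-6 predicate.
#' @param criterion_funs optional named list of criterion overrides.
#' @return one-row tibble with `c1`..`c6`, `score`, `guide_defined`, guide
#'   and star fields, duplex geometry and read totals.
#' @export
compute_quality_score <- function(locus, mfei_star_threshold = -0.8,
                                  min_arm_reads = 10, min_total_reads = 100,
                                  guide_min_freq = 1 / 3,
                                  precision_frac = 0.75, guide_window = 3,
                                  star_window = 5,
                                  duplex_rule = duplex_rule_default,
                                  criterion_funs = NULL) {
  hp <- locus$hairpin
  guide <- select_guide(locus, min_freq = guide_min_freq)
  guide_defined <- !is.null(guide)
  star_pos <- NA_integer_
  if (guide_defined) {
    star_pos <- tryCatch(
      expected_star_position(hp$structure, guide$local_start, guide$length),
      error = function(e) NA_integer_
    )
  }
  crit <- function(name, default_expr) {
    f <- criterion_funs[[name]]
    if (!is.null(f)) isTRUE(f(locus, guide, star_pos)) else
      isTRUE(default_expr)
  }
  c1 <- crit("c1", criterion1_stability(hp$mfei,
                                        threshold = mfei_star_threshold))
  c2 <- crit("c2", criterion2_reads(locus, min_arm_reads = min_arm_reads,
                                    min_total_reads = min_total_reads))
  c3 <- crit("c3", guide_defined)
  c4 <- guide_defined && crit("c4", criterion4_precision(
    locus, guide, star_pos, frac = precision_frac,
    guide_window = guide_window, star_window = star_window))
  c5 <- guide_defined && crit("c5", criterion5_star_expressed(
    locus, star_pos, star_window = star_window))
  c6 <- guide_defined && crit("c6", criterion6_duplex_stability(
    hp, guide, rule = duplex_rule))
  if (!guide_defined) c3 <- FALSE
  score <- sum(c1, c2, c3, c4, c5, c6)
  r <- locus$reads
  star_reads <- if (!is.na(star_pos)) {
    r[abs(r$local_start - star_pos) <= star_window, ]
  } else r[0, ]
  star_top <- if (nrow(star_reads)) {
    star_reads |>
      arrange(desc(.data$count), .data$local_start, .data$sequence) |>
      dplyr::slice(1)
  } else NULL
  tibble(
    c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5, c6 = c6,
    score = as.integer(score),
    guide_defined = guide_defined,
    guide_seq = if (guide_defined) guide$sequence else NA_character_,
    guide_local_start = if (guide_defined) guide$local_start else
      NA_integer_,
    guide_len = if (guide_defined) guide$length else NA_integer_,
    guide_arm = if (guide_defined) guide$arm else NA_character_,
    guide_count = if (guide_defined) guide$count else NA_integer_,
    guide_freq = if (guide_defined) guide$freq else NA_real_,
    star_expected_start = as.integer(star_pos),
    star_seq = if (!is.null(star_top)) star_top$sequence else NA_character_,
    star_count = as.integer(sum(star_reads$count)),
    total_reads = as.integer(sum(r$count)),
    n_unique_reads = nrow(r)
  )
}
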