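# Hairpin selection and thermodynamic statistics. Candidate loci are
# folded with RNALfold, reduced to their best single stem-loop, and scored
# with MFE, AMFE (MFE per 100 nt) and MFEI (AMFE / GC%).

#' Select the best miRNA-compatible stem-loop from local folds
#'
#' Each locally stable structure is trimmed of external unpaired tails,
#' dissolved into single stem-loop components when multibranched, and kept
#' when its length lies in `[min_len, max_len]` and at least
#' `min_paired_frac` of its bases are paired. The component with the
#' lowest free energy (re-evaluated on the trimmed subsequence) wins.
#'
#' @param folds tibble from [fold_locally()].
#' @param sequence the folded RNA sequence.
#' @param min_len,max_len precursor length bounds in nt.
#' @param min_paired_frac minimum fraction of paired bases.
#' @return one-row tibble (`local_start`, `length`, `sequence`,
#'   `structure`, `mfe`) or `NULL` when nothing qualifies.
#' @export
select_stemloop <- function(folds, sequence, min_len = 60, max_len = 350,
                            min_paired_frac = 0.5) {
  sequence <- as_rna(sequence)
  if (!nrow(folds)) return(NULL)
  cands <- purrr::map(seq_len(nrow(folds)), function(k) {
    comp <- stemloop_components(folds$structure[k])
    if (!nrow(comp)) return(NULL)
    comp |>
      mutate(
        local_start = folds$local_start[k] + .data$start - 1L,
        length = .data$end - .data$start + 1L,
        structure = substring(folds$structure[k], .data$start, .data$end)
      ) |>
      select("local_start", "length", "structure")
  })
  cands <- bind_rows(purrr::compact(cands))
  if (!nrow(cands)) return(NULL)
  cands <- cands |>
    dplyr::distinct(.data$local_start, .data$length, .keep_all = TRUE) |>
    mutate(
      paired_frac = purrr::map_dbl(.data$structure, function(s) {
        1 - nchar(gsub("[^.]", "", s)) / nchar(s)
      })
    ) |>
    filter(.data$length >= min_len, .data$length <= max_len,
           .data$paired_frac >= min_paired_frac)
  if (!nrow(cands)) return(NULL)
  cands$sequence <- substr(rep(sequence, nrow(cands)),
                           cands$local_start + 1L,
                           cands$local_start + cands$length)
  cands$mfe <- eval_energy(cands$sequence, cands$structure)
  best <- cands[which.min(cands$mfe), ]
  select(best, "local_start", "length", "sequence", "structure", "mfe")
}

#' Thermodynamic statistics of a hairpin
#'
#' Computes MFE (via RNAeval when not supplied), AMFE (MFE normalized per
#' 100 nt) and MFEI (AMFE divided by GC percentage, GC expressed in
#' percent so that genuine precursors typically fall below -0.6).
#'
#' @param sequence RNA string.
#' @param structure dot-bracket string of the same length.
#' @param mfe optional known free energy in kcal/mol.
#' @return one-row tibble: `mfe`, `amfe`, `mfei`, `gc_percent`, `length`.
#' @export
thermo_stats <- function(sequence, structure, mfe = NULL) {
  sequence <- as_rna(sequence)
  stopifnot(nchar(sequence) == nchar(structure))
  if (is.null(mfe)) mfe <- eval_energy(sequence, structure)
  len <- nchar(sequence)
  gc <- gc_percent_of(sequence)
  amfe <- mfe / len * 100
  mfei <- if (gc == 0) NA_real_ else amfe / gc
  if (gc == 0) warn("GC content is zero; MFEI undefined, candidate rejected")
  tibble(mfe = mfe, amfe = amfe, mfei = mfei, gc_percent = gc, length = len)
}

#' Optional MFEI prefilter
#'
#' When enabled, keeps only hairpins with MFEI strictly below `threshold`.
#' More than 96% of annotated plant precursors fall below -0.6 while
#' pseudo-hairpins generally do not, so this is an effective cheap filter.
#'
#' @param hairpins tibble with an `mfei` column.
#' @param threshold strict upper bound (default -0.6).
#' @param enabled logical; pass-through when `FALSE`.
#' @return filtered tibble.
#' @export
mfei_prefilter <- function(hairpins, threshold = -0.6, enabled = TRUE) {
  if (!enabled) return(hairpins)
  filter(hairpins, !is.na(.data$mfei), .data$mfei < threshold)
}

with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# One Eulerian-path dinucleotide-preserving shuffle (Altschul-Erickson).
# Preserves all 16 dinucleotide counts and the first/last nucleotide.
shuffle_dinucleotide_once <- function(chars) {
  n <- length(chars)
  verts <- unique(chars)
  from <- chars[-n]
  to <- chars[-1]
  last_v <- chars[n]
  out_edges <- split(to, factor(from, levels = verts))
  repeat {
    last_edge <- list()
    ok <- TRUE
    for (v in verts) {
      if (v == last_v || !length(out_edges[[v]])) next
      last_edge[[v]] <- sample(out_edges[[v]], 1)
    }
    # the chosen last edges must form a tree converging to last_v
    for (v in names(last_edge)) {
      cur <- v
      seen <- character()
      while (cur != last_v) {
        if (cur %in% seen || is.null(last_edge[[cur]])) {
          ok <- FALSE
          break
        }
        seen <- c(seen, cur)
        cur <- last_edge[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  # order remaining edges randomly per vertex, reserved last edge at the end
  edge_order <- lapply(setNames(verts, verts), function(v) {
    e <- out_edges[[v]]
    if (!is.null(last_edge[[v]])) {
      idx <- match(last_edge[[v]], e)
      e <- e[-idx]
    }
    if (length(e) > 1) e <- sample(e)
    c(e, last_edge[[v]])
  })
  used <- setNames(integer(length(verts)), verts)
  out <- character(n)
  out[1] <- chars[1]
  cur <- chars[1]
  for (i in 2:n) {
    used[cur] <- used[cur] + 1L
    nxt <- edge_order[[cur]][used[cur]]
    out[i] <- nxt
    cur <- nxt
  }
  out
}

#' Dinucleotide-preserving sequence shuffles
#'
#' Generates random sequences with exactly the same dinucleotide
#' composition (and first/last nucleotide) as the input, by sampling random
#' Eulerian paths on the dinucleotide transition graph.
#'
#' @param sequence RNA string, at least 4 nt.
#' @param n number of shuffles.
#' @param seed optional integer seed (local RNG; global state untouched).
#' @return character vector of `n` shuffled sequences.
#' @export
dinucleotide_shuffle <- function(sequence, n = 1, seed = NULL) {
  sequence <- as_rna(sequence)
  check_rna(sequence)
  if (nchar(sequence) < 4) abort("sequence too short to shuffle (< 4 nt)")
  chars <- strsplit(sequence, "")[[1]]
  with_local_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(shuffle_dinucleotide_once(chars), collapse = "")
    }, character(1))
  })
}

#' Folding-stability significance by dinucleotide shuffling
#'
#' Compares the global MFE of a sequence with the MFE distribution of `n`
#' dinucleotide-preserving shuffles and reports the pseudocount-corrected
#' empirical p-value `(k + 1) / (n + 1)` where `k` shuffles fold at least
#' as stably as the observed sequence.
#'
#' @param sequence RNA string.
#' @param n number of shuffles (>= 10).
#' @param seed optional integer seed.
#' @param mfe optional observed MFE; computed by a global fold when `NULL`.
#' @return one-row tibble: `n_shuffles`, `n_as_stable`, `empirical_p`,
#'   `observed_mfe`.
#' @export
shuffle_significance <- function(sequence, n = 100, seed = NULL, mfe = NULL) {
  if (n < 10) abort("n must be >= 10")
  sequence <- as_rna(sequence)
  if (is.null(mfe)) mfe <- fold_global(sequence)$mfe
  shuffles <- dinucleotide_shuffle(sequence, n = n, seed = seed)
  shuffle_mfe <- fold_global(shuffles)$mfe
  k <- sum(shuffle_mfe <= mfe)
  tibble(n_shuffles = as.integer(n), n_as_stable = as.integer(k),
         empirical_p = (k + 1) / (n + 1), observed_mfe = mfe)
}

#' Build a hairpin record from a known sequence and structure
#'
#' Assembles the per-precursor record (thermodynamics plus arm/loop
#' partition) used by the scoring stage, for callers that already have a
#' structure — planted fixtures, externally folded precursors.
#'
#' @param sequence RNA string.
#' @param structure dot-bracket string (single terminal loop).
#' @param chrom,start,strand genomic placement of the precursor.
#' @param mfe optional known free energy (RNAeval is used when `NULL`).
#' @return one-row hairpin tibble as produced by [fold_candidate()].
#' @export
hairpin_from_structure <- function(sequence, structure, chrom = "local",
                                   start = 0L, strand = "+", mfe = NULL) {
  sequence <- as_rna(sequence)
  stopifnot(nchar(sequence) == nchar(structure))
  stats <- thermo_stats(sequence, structure, mfe = mfe)
  part <- hairpin_partition(structure)
  tibble(
    chrom = chrom, strand = strand, start = as.integer(start),
    end = as.integer(start) + nchar(sequence),
    sequence = sequence, structure = structure,
    mfe = stats$mfe, amfe = stats$amfe, mfei = stats$mfei,
    gc_percent = stats$gc_percent, length = stats$length,
    loop_start = part$loop[1], loop_end = part$loop[2]
  )
}

#' Fold a candidate locus into its precursor hairpin
#'
#' Convenience composition of [fold_locally()], [select_stemloop()] and
#' [thermo_stats()] for one candidate locus.
#'
#' @param candidate one-row candidate tibble ([discover_loci()]).
#' @param genome [Biostrings::DNAStringSet].
#' @param margin nt of genomic context added on each side before folding
#'   (precursor ends usually extend past the read-covered interval).
#' @param max_span RNALfold span cap.
#' @inheritParams select_stemloop
#' @return one-row hairpin tibble with genomic coordinates, sequence,
#'   structure, thermodynamics and loop partition, or `NULL`.
#' @export
fold_candidate <- function(candidate, genome, margin = 30, max_span = 350,
                           min_len = 60, max_len = 350,
                           min_paired_frac = 0.5) {
  stopifnot(nrow(candidate) == 1)
  chrom_len <- Biostrings::width(genome[candidate$chrom])
  candidate$start <- max(0L, candidate$start - as.integer(margin))
  candidate$end <- min(chrom_len, candidate$end + as.integer(margin))
  seq <- extract_genome(genome, candidate$chrom, candidate$start,
                        candidate$end, candidate$strand)
  if (nchar(seq) < 40) return(NULL)
  folds <- fold_locally(seq, max_span = max_span)
  best <- select_stemloop(folds, seq, min_len = min_len, max_len = max_len,
                          min_paired_frac = min_paired_frac)
  if (is.null(best)) return(NULL)
  stats <- thermo_stats(best$sequence, best$structure, mfe = best$mfe)
  part <- hairpin_partition(best$structure)
  gstart <- if (candidate$strand == "+") {
    candidate$start + best$local_start
  } else {
    candidate$end - best$local_start - best$length
  }
  tibble(
    chrom = candidate$chrom, strand = candidate$strand,
    start = gstart, end = gstart + best$length,
    sequence = best$sequence, structure = best$structure,
    mfe = stats$mfe, amfe = stats$amfe, mfei = stats$mfei,
    gc_percent = stats$gc_percent, length = stats$length,
    loop_start = part$loop[1], loop_end = part$loop[2]
  )
}
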