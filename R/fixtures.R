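# Synthetic data with known ground truth: planted hairpin precursors,
# two-peak read clouds (dominant guide + star at the 2-nt-overhang pairing
# position + sparse background), multi-mapping repeat traps and mask
# features. Everything is seeded explicitly; no global RNG state is used.

sample_bases <- function(n, gc_frac = 0.5) {
  probs <- c(A = (1 - gc_frac) / 2, C = gc_frac / 2, G = gc_frac / 2,
             U = (1 - gc_frac) / 2)
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Generate a synthetic hairpin precursor
#'
#' Builds a random stem of `stem_len` base pairs (the 3' arm is the
#' reverse complement of the 5' arm), a loop, and `n_mismatches` planted
#' mismatches, returning the sequence and its intended dot-bracket.
#'
#' @param stem_len stem length in base pairs (>= 18).
#' @param loop_len loop length in nt (>= 3).
#' @param n_mismatches number of stem positions mutated to non-pairing
#'   bases.
#' @param gc_frac GC fraction of the stem.
#' @param seed optional integer seed.
#' @return list with `sequence` and `structure`.
#' @export
make_hairpin <- function(stem_len, loop_len, n_mismatches = 0,
                         gc_frac = 0.5, seed = NULL) {
  if (stem_len < 18) abort("stem_len must be >= 18")
  if (loop_len < 3) abort("loop_len must be >= 3")
  if (n_mismatches > stem_len) abort("more mismatches than stem positions")
  with_local_seed(seed, {
    arm5 <- sample_bases(stem_len, gc_frac)
    loop <- sample_bases(loop_len, 0.3)
    arm3 <- rev(chartr("ACGU", "UGCA", arm5))
    struct5 <- rep("(", stem_len)
    struct3 <- rep(")", stem_len)
    if (n_mismatches > 0) {
      pos <- sample(seq_len(stem_len), n_mismatches)
      for (p in pos) {
        partner <- stem_len - p + 1L
        repl <- setdiff(c("A", "C", "G", "U"), arm3[partner])
        legal <- vapply(repl, function(b) {
          paste0(sort(c(b, arm5[p])), collapse = "") %in%
            c("CG", "AU", "GU")
        }, logical(1))
        arm3[partner] <- sample(repl[!legal], 1)
        struct5[p] <- "."
        struct3[partner] <- "."
      }
    }
    list(
      sequence = paste(c(arm5, loop, arm3), collapse = ""),
      structure = paste(c(struct5, rep(".", loop_len), struct3),
                        collapse = "")
    )
  })
}

#' Plant a specific guide miRNA in a perfect hairpin
#'
#' Builds a precursor in which `guide_seq` sits on the 5' arm of a fully
#' complementary stem, so the passenger strand occupies the position
#' implied by the canonical 2-nt 3' overhang geometry.
#'
#' @param guide_seq guide RNA string.
#' @param pad nt of random stem on the 5' side of the guide (>= 2 so the
#'   star's 2-nt overhang stays inside the stem).
#' @param loop_len loop length in nt.
#' @param seed optional integer seed.
#' @param chrom,genomic_start,strand genomic placement of the locus.
#' @return a planted-locus list: `sequence`, `structure`, `guide_seq`,
#'   `guide_local_start`, `guide_len`, `star_local_start`, `star_seq`,
#'   `chrom`, `genomic_start`, `strand`.
#' @export
make_planted_locus <- function(guide_seq, pad = 4, loop_len = 8,
                               seed = NULL, chrom = "chr1",
                               genomic_start = 0L, strand = "+") {
  if (pad < 2) abort("pad must be >= 2")
  guide_seq <- as_rna(guide_seq)
  check_rna(guide_seq)
  L <- nchar(guide_seq)
  with_local_seed(seed, {
    p5 <- sample_bases(pad, 0.5)
    arm5 <- c(p5, strsplit(guide_seq, "")[[1]])
    loop <- sample_bases(loop_len, 0.3)
    arm3 <- rev(chartr("ACGU", "UGCA", arm5))
    seq <- paste(c(arm5, loop, arm3), collapse = "")
    n_arm <- pad + L
    struct <- paste(c(rep("(", n_arm), rep(".", loop_len),
                      rep(")", n_arm)), collapse = "")
    star_start <- n_arm + loop_len + 2L
    list(
      sequence = seq, structure = struct,
      guide_seq = guide_seq, guide_local_start = pad, guide_len = L,
      star_local_start = star_start,
      star_seq = substr(seq, star_start + 1L, star_start + L),
      chrom = chrom, genomic_start = as.integer(genomic_start),
      strand = strand
    )
  })
}

local_to_genomic <- function(planted, local_start, len) {
  n <- nchar(planted$sequence)
  if (planted$strand == "+") {
    planted$genomic_start + local_start
  } else {
    planted$genomic_start + n - local_start - len
  }
}

#' Generate a two-peak read cloud for a planted locus
#'
#' Emits `guide_copies` of the guide read at the guide offset,
#' `star_copies` at the star offset, and background degradation reads with
#' uniform random starts and Poisson(1)+1 copy counts until exactly
#' `background_copies` copies are placed. With `guide_jitter > 0` a
#' fraction of guide copies is displaced by up to that many nt, creating
#' isomiR-like neighbours.
#'
#' @param planted planted-locus list ([make_planted_locus()]).
#' @param guide_copies,star_copies,background_copies copy totals.
#' @param guide_jitter max displacement of non-canonical guide copies.
#' @param n_background_unique number of distinct background reads to aim
#'   for (the last one absorbs any remainder).
#' @param seed optional integer seed.
#' @return tibble of read alignments in genomic coordinates.
#' @export
make_read_cloud <- function(planted, guide_copies = 71, star_copies = 27,
                            background_copies = 16, guide_jitter = 0,
                            n_background_unique = 5, seed = NULL) {
  n <- nchar(planted$sequence)
  take <- function(local_start, len, count) {
    local_start <- max(0L, min(local_start, n - len))
    tibble(
      chrom = planted$chrom,
      start = local_to_genomic(planted, local_start, len),
      end = local_to_genomic(planted, local_start, len) + len,
      strand = planted$strand,
      sequence = substr(planted$sequence, local_start + 1L,
                        local_start + len),
      count = as.integer(count), n_hits = 1L
    )
  }
  with_local_seed(seed, {
    out <- list()
    if (guide_copies > 0) {
      jittered <- 0L
      if (guide_jitter > 0) {
        jittered <- min(guide_copies - 1L,
                        stats::rbinom(1, guide_copies, 0.15))
      }
      out <- c(out, list(take(planted$guide_local_start, planted$guide_len,
                              guide_copies - jittered)))
      while (jittered > 0) {
        d <- sample(setdiff(-guide_jitter:guide_jitter, 0), 1)
        k <- min(jittered, 1L + stats::rpois(1, 1))
        out <- c(out, list(take(planted$guide_local_start + d,
                                planted$guide_len, k)))
        jittered <- jittered - k
      }
    }
    if (star_copies > 0) {
      out <- c(out, list(take(planted$star_local_start, planted$guide_len,
                              star_copies)))
    }
    remaining <- background_copies
    i <- 0L
    while (remaining > 0) {
      i <- i + 1L
      len <- sample(18:24, 1)
      ls <- sample(0:(n - len), 1)
      k <- if (i >= n_background_unique) remaining else
        min(remaining, 1L + stats::rpois(1, 1))
      out <- c(out, list(take(ls, len, k)))
      remaining <- remaining - k
    }
    reads <- bind_rows(out) |>
      group_by(.data$chrom, .data$start, .data$end, .data$strand,
               .data$sequence, .data$n_hits) |>
      summarise(count = as.integer(sum(.data$count)), .groups = "drop") |>
      select("chrom", "start", "end", "strand", "sequence", "count",
             "n_hits")
    validate_reads(order_reads(reads))
  })
}

#' The canonical worked-example fixture
#'
#' A locus with 114 read copies in 7 unique reads: a dominant 21-nt guide
#' with 71 copies (62% of the locus), a passenger read with 27 copies at
#' the 2-nt-overhang pairing position, and 16 background copies spread
#' over 5 unique degradation reads.
#'
#' @param seed integer seed (default 42).
#' @param chrom,genomic_start,strand genomic placement.
#' @return list with `planted` and `reads`.
#' @export
canonical_locus_fixture <- function(seed = 42, chrom = "chr1",
                                    genomic_start = 1000L, strand = "+") {
  planted <- make_planted_locus(
    "AGAUAUUAGUGCGGUUCAAUC", pad = 7, loop_len = 10, seed = seed,
    chrom = chrom, genomic_start = genomic_start, strand = strand
  )
  reads <- make_read_cloud(planted, guide_copies = 71, star_copies = 27,
                           background_copies = 16, guide_jitter = 0,
                           n_background_unique = 5, seed = seed + 1L)
  # exactly 7 unique reads, with the 16 background copies clear of the
  # guide [-3,+3] and star [-5,+5] windows so the printed per-peak counts
  # stay exact: regenerate the background until the layout complies
  cloud_ok <- function(reads) {
    n <- nchar(planted$sequence)
    ls <- if (planted$strand == "+") {
      reads$start - planted$genomic_start
    } else {
      planted$genomic_start + n - reads$end
    }
    is_peak <- ls %in% c(planted$guide_local_start,
                         planted$star_local_start) &
      reads$end - reads$start == planted$guide_len
    bg <- ls[!is_peak]
    nrow(reads) == 7L && sum(reads$count) == 114L &&
      sum(reads$count[!is_peak]) == 16L &&
      all(abs(bg - planted$guide_local_start) > 3L) &&
      all(abs(bg - planted$star_local_start) > 5L)
  }
  s <- seed + 1L
  while (!cloud_ok(reads)) {
    s <- s + 1L
    reads <- make_read_cloud(planted, guide_copies = 71, star_copies = 27,
                             background_copies = 16, guide_jitter = 0,
                             n_background_unique = 5, seed = s)
  }
  list(planted = planted, reads = reads)
}

#' Build a synthetic genome around planted loci
#'
#' Inserts planted precursors into a random background sequence and
#' optionally plants a multi-copy repeat (a multi-mapping trap) and CDS
#' mask features. Returns the genome, the updated loci and truth/mask
#' annotation tibbles.
#'
#' @param loci list of planted-locus lists; their `genomic_start` fields
#'   are reassigned to non-overlapping, evenly spaced positions unless
#'   `keep_positions` is `TRUE`.
#' @param length genome length in nt.
#' @param seed optional integer seed.
#' @param chrom chromosome name.
#' @param repeat_copies copies of an 80-nt TE-like repeat to plant (0 for
#'   none).
#' @param n_cds number of 300-nt CDS mask features to plant.
#' @param keep_positions honour the loci's own `genomic_start`.
#' @return list with `genome` (DNAStringSet), `loci`, `truth` (feature
#'   tibble of planted precursors), `mask` (CDS features tibble) and
#'   `repeat_loci`.
#' @export
make_genome <- function(loci = list(), length = 10000, seed = NULL,
                        chrom = "chr1", repeat_copies = 0, n_cds = 0,
                        keep_positions = FALSE) {
  with_local_seed(seed, {
    base <- sample_bases(length, 0.35)
    n_loci <- base::length(loci)
    slots <- list()
    if (n_loci > 0 && !keep_positions) {
      step <- floor(length / (n_loci + 1))
      for (i in seq_len(n_loci)) {
        loci[[i]]$genomic_start <- as.integer(i * step)
        loci[[i]]$chrom <- chrom
      }
    }
    for (lc in loci) {
      s <- lc$sequence
      if (lc$strand == "-") s <- revcomp_rna(s)
      pos <- lc$genomic_start
      if (pos < 0 || pos + nchar(s) > length) abort("locus outside genome")
      span <- (pos + 1L):(pos + nchar(s))
      if (any(vapply(slots, function(x) any(span %in% x), logical(1)))) {
        abort("planted loci overlap")
      }
      slots <- c(slots, list(span))
      base[span] <- strsplit(s, "")[[1]]
    }
    free_slot <- function(w) {
      for (attempt in 1:200) {
        pos <- sample(0:(length - w), 1)
        span <- (pos + 1L):(pos + w)
        if (!any(vapply(slots, function(x) any(span %in% x),
                        logical(1)))) {
          slots <<- c(slots, list(span))
          return(pos)
        }
      }
      abort("could not place feature without overlap")
    }
    repeat_loci <- tibble(chrom = character(), start = integer(),
                          end = integer(), strand = character())
    repeat_seq <- NULL
    if (repeat_copies > 0) {
      repeat_seq <- paste(sample_bases(80, 0.4), collapse = "")
      for (i in seq_len(repeat_copies)) {
        pos <- free_slot(80L)
        base[(pos + 1L):(pos + 80L)] <- strsplit(repeat_seq, "")[[1]]
        repeat_loci <- bind_rows(repeat_loci,
                                 tibble(chrom = chrom, start = pos,
                                        end = pos + 80L, strand = "+"))
      }
    }
    mask <- tibble(chrom = character(), start = integer(), end = integer(),
                   strand = character(), type = character(),
                   id = character())
    for (i in seq_len(n_cds)) {
      pos <- free_slot(300L)
      mask <- bind_rows(mask, tibble(chrom = chrom, start = pos,
                                     end = pos + 300L, strand = "+",
                                     type = "CDS",
                                     id = paste0("cds", i)))
    }
    truth <- if (n_loci > 0) {
      bind_rows(purrr::map(seq_len(n_loci), function(i) {
        lc <- loci[[i]]
        tibble(chrom = lc$chrom, start = lc$genomic_start,
               end = lc$genomic_start + nchar(lc$sequence),
               strand = lc$strand, type = "miRNA_primary_transcript",
               id = paste0("planted", i))
      }))
    } else {
      tibble(chrom = character(), start = integer(), end = integer(),
             strand = character(), type = character(), id = character())
    }
    genome <- Biostrings::DNAStringSet(
      setNames(paste(as_dna(base), collapse = ""), chrom)
    )
    list(genome = genome, loci = loci, truth = truth, mask = mask,
         repeat_loci = repeat_loci, repeat_seq = repeat_seq)
  })
}

count_genomic_hits <- function(sequences, genome) {
  vapply(sequences, function(s) {
    pat <- Biostrings::DNAString(as_dna(s))
    hits <- sum(Biostrings::vcountPattern(pat, genome)) +
      sum(Biostrings::vcountPattern(Biostrings::reverseComplement(pat),
                                    genome))
    max(1L, as.integer(hits))
  }, integer(1), USE.NAMES = FALSE)
}

#' Generate a complete synthetic dataset
#'
#' A genome with planted miRNA loci, their read clouds, optional repeat
#' reads (multi-mapping) and mask features, with every read's genome-wide
#' hit count computed by exact matching. This is the ground-truth input
#' for end-to-end pipeline tests.
#'
#' @param n_loci number of planted miRNA loci.
#' @param length genome length.
#' @param seed integer seed driving every random choice.
#' @param guide_copies,star_copies,background_copies per-locus read-cloud
#'   totals.
#' @param stem_len,loop_len,n_mismatches hairpin geometry.
#' @param repeat_copies,repeat_read_count multi-mapping trap: copies of a
#'   planted repeat and copy count of the read generated from each copy.
#' @param n_cds CDS mask features to plant.
#' @param minus_strand_frac fraction of loci planted on the minus strand.
#' @param n_noise_reads unplanted degradation reads scattered uniformly
#'   over the genome (the background of a library without miRNA loci).
#' @return list with `genome`, `reads`, `loci`, `truth`, `mask`.
#' @export
make_dataset <- function(n_loci = 1, length = 6000, seed = 1,
                         guide_copies = 60, star_copies = 15,
                         background_copies = 10, stem_len = 28,
                         loop_len = 10, n_mismatches = 0,
                         repeat_copies = 0, repeat_read_count = 3,
                         n_cds = 0, minus_strand_frac = 0,
                         n_noise_reads = 0) {
  loci <- with_local_seed(seed, {
    purrr::map(seq_len(n_loci), function(i) {
      guide <- paste(sample_bases(21, 0.5), collapse = "")
      strand <- if (runif(1) < minus_strand_frac) "-" else "+"
      make_planted_locus(guide, pad = max(2, stem_len - 21), loop_len = loop_len,
                         strand = strand)
    })
  })
  gen <- make_genome(loci, length = length, seed = seed + 1000L,
                     repeat_copies = repeat_copies, n_cds = n_cds)
  reads <- purrr::imap(gen$loci, function(lc, i) {
    make_read_cloud(lc, guide_copies = guide_copies,
                    star_copies = star_copies,
                    background_copies = background_copies,
                    seed = seed + 2000L + i)
  }) |> bind_rows()
  if (repeat_copies > 0 && nrow(gen$repeat_loci)) {
    rep_reads <- purrr::map(seq_len(nrow(gen$repeat_loci)), function(i) {
      r <- gen$repeat_loci[i, ]
      tibble(chrom = r$chrom, start = r$start + 10L, end = r$start + 31L,
             strand = "+",
             sequence = as_rna(substr(gen$repeat_seq, 11, 31)),
             count = as.integer(repeat_read_count), n_hits = 1L)
    }) |> bind_rows()
    reads <- bind_rows(reads, rep_reads)
  }
  if (n_noise_reads > 0) {
    noise <- with_local_seed(seed + 5000L, {
      purrr::map(seq_len(n_noise_reads), function(i) {
        len <- sample(18:24, 1)
        pos <- sample(0:(length - len), 1)
        strand <- sample(c("+", "-"), 1)
        tibble(chrom = names(gen$genome)[1], start = pos, end = pos + len,
               strand = strand,
               sequence = extract_genome(gen$genome,
                                         names(gen$genome)[1], pos,
                                         pos + len, strand),
               count = 1L + stats::rpois(1, 0.5), n_hits = 1L)
      }) |> bind_rows()
    })
    reads <- bind_rows(reads, noise)
  }
  if (nrow(reads)) {
    reads <- reads |>
      group_by(.data$chrom, .data$start, .data$end, .data$strand,
               .data$sequence) |>
      summarise(count = as.integer(sum(.data$count)), .groups = "drop") |>
      mutate(n_hits = 1L)
    reads$n_hits <- count_genomic_hits(reads$sequence, gen$genome)
    reads <- validate_reads(order_reads(
      select(reads, "chrom", "start", "end", "strand", "sequence",
             "count", "n_hits")))
  } else {
    reads <- empty_reads()
  }
  list(genome = gen$genome, reads = reads, loci = gen$loci,
       truth = gen$truth, mask = gen$mask)
}
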