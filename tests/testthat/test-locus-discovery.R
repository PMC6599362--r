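mk_reads_at <- function(starts, counts, chrom = "chr1", strand = "+",
                        len = 21) {
  dplyr::bind_rows(lapply(seq_along(starts), function(i) {
    tibble::tibble(chrom = chrom, start = starts[i],
                   end = starts[i] + len, strand = strand,
                   sequence = strrep("A", len),
                   count = as.integer(counts[i]), n_hits = 1L)
  }))
}

test_that("pairing_matrix matches hand-checked duplexes", {
  expect_equal(pairing_matrix("GGGG", "CCCC"), 4) # all C-G
  expect_equal(pairing_matrix("GGGG", "AAAA"), 0) # no legal pair
  expect_equal(pairing_matrix("GUGU", "GUGU"), 4) # wobble both ways
  expect_error(pairing_matrix("GGXG", "CCCC"), "invalid")
  expect_error(pairing_matrix("", "CCCC"), "non-empty")
})

test_that("pairing_matrix agrees with the brute-force oracle on random short sequences", {
  withr::with_seed(99, {
    for (i in 1:60) {
      a <- random_rna(sample(3:7, 1))
      b <- random_rna(sample(3:7, 1))
      expect_equal(pairing_matrix(a, b), oracle_pairing(a, b),
                   info = paste(a, b))
    }
  })
})

test_that("duplex pairing score is symmetric", {
  withr::with_seed(7, {
    for (i in 1:25) {
      a <- random_rna(sample(10:25, 1))
      b <- random_rna(sample(10:25, 1))
      expect_equal(pairing_matrix(a, b), pairing_matrix(b, a))
    }
  })
})

test_that("call_peaks merges gap-separated reads and keeps a lone cluster", {
  # one cluster of 114 copies across close reads
  reads <- mk_reads_at(c(1000, 1004, 1030), c(71, 27, 16))
  peaks <- call_peaks(reads)
  expect_equal(nrow(peaks), 1)
  expect_equal(peaks$total_count, 114)
  expect_equal(peaks$start, 1000)
  expect_equal(peaks$end, 1051)
  expect_equal(call_peaks(mk_reads_at(integer(), integer())) |> nrow(), 0)
})

test_that("two-means separates signal from background clusters", {
  # counts {1000, 1}: sorted split of log10 counts {3, 0} isolates the
  # signal cluster; the 1-copy cluster is below the absolute floor
  reads <- mk_reads_at(c(1000, 3000), c(1000, 1))
  peaks <- call_peaks(reads)
  expect_equal(nrow(peaks), 1)
  expect_equal(peaks$total_count, 1000)
  # the floor rescues moderately expressed low-group clusters
  reads2 <- mk_reads_at(c(1000, 3000), c(1000, 50))
  expect_equal(nrow(call_peaks(reads2)), 2)
  # equal counts: no split, all kept
  reads3 <- mk_reads_at(c(1000, 3000, 5000), c(7, 7, 7))
  expect_equal(nrow(call_peaks(reads3)), 3)
})

test_that("reads further apart than cluster_gap form separate clusters", {
  reads <- mk_reads_at(c(1000, 1052), c(40, 40)) # ends at 1021; gap 31
  expect_equal(nrow(call_peaks(reads, cluster_gap = 30)), 2)
  reads2 <- mk_reads_at(c(1000, 1051), c(40, 40)) # gap 30: merged
  expect_equal(nrow(call_peaks(reads2, cluster_gap = 30)), 1)
})

test_that("peaks on one strand never overlap", {
  withr::with_seed(31, {
    for (i in 1:5) {
      starts <- sort(sample(0:4000, 25))
      reads <- mk_reads_at(starts, sample(1:80, 25, replace = TRUE))
      peaks <- call_peaks(reads)
      if (nrow(peaks) > 1) {
        expect_true(all(peaks$start[-1] >= peaks$end[-nrow(peaks)]))
      }
    }
  })
})

genome_with <- function(pieces, pad = 400, seed = 1) {
  # all-A filler cannot pair with an all-G peak, so pairing signal can
  # only come from the planted reverse complement
  filler <- strrep("A", 20000)
  seqs <- substr(filler, 1, pad)
  for (p in pieces) {
    seqs <- paste0(seqs, p$dna,
                   substr(filler, nchar(seqs) + nchar(p$dna) + 1,
                          nchar(seqs) + nchar(p$dna) + p$gap_after))
  }
  Biostrings::DNAStringSet(setNames(seqs, "chr1"))
}

test_that("find_duplex_partner locates a reverse complement within the radius", {
  peak_rna <- strrep("G", 21)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(chartr("U", "T", peak_rna))))
  genome <- genome_with(list(
    list(dna = chartr("U", "T", peak_rna), gap_after = 60),
    list(dna = rc, gap_after = 0)
  ))
  peak <- tibble::tibble(chrom = "chr1", strand = "+", start = 400,
                         end = 421, total_count = 50L, max_depth = 50L,
                         n_reads = 1L)
  cand <- find_duplex_partner(peak, genome)
  expect_false(is.null(cand))
  expect_equal(cand$partner_offset, 60)
  expect_equal(cand$pairing_score, 21)
  expect_equal(cand$start, 400)
  expect_equal(cand$end, 421 + 60 + 21)
  # candidate contains the peak entirely
  expect_true(cand$start <= peak$start && cand$end >= peak$end)
})

test_that("no partner is reported beyond the search radius", {
  peak_rna <- strrep("G", 21)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(chartr("U", "T", peak_rna))))
  genome <- genome_with(list(
    list(dna = chartr("U", "T", peak_rna), gap_after = 351),
    list(dna = rc, gap_after = 0)
  ))
  peak <- tibble::tibble(chrom = "chr1", strand = "+", start = 400,
                         end = 421, total_count = 50L, max_depth = 50L,
                         n_reads = 1L)
  expect_null(find_duplex_partner(peak, genome))
})

test_that("a poly-A peak in a poly-A context has no partner", {
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 2000)))
  peak <- tibble::tibble(chrom = "chr1", strand = "+", start = 900,
                         end = 921, total_count = 50L, max_depth = 50L,
                         n_reads = 1L)
  expect_null(find_duplex_partner(peak, genome))
})

test_that("search range is clipped at contig edges without error", {
  peak_rna <- strrep("G", 21)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(chartr("U", "T", peak_rna))))
  seqs <- paste0(chartr("U", "T", peak_rna), strrep("AT", 30), rc)
  genome <- Biostrings::DNAStringSet(setNames(seqs, "chr1"))
  peak <- tibble::tibble(chrom = "chr1", strand = "+", start = 0,
                         end = 21, total_count = 50L, max_depth = 50L,
                         n_reads = 1L)
  cand <- find_duplex_partner(peak, genome)
  expect_false(is.null(cand))
  expect_equal(cand$pairing_score, 21)
})
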