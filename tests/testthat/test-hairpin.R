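test_that("fold_locally recovers a planted inverted repeat and rejects homopolymers", {
  hp <- make_hairpin(30, 6, seed = 1)
  folds <- fold_locally(hp$sequence)
  expect_gt(nrow(folds), 0)
  best <- folds[which.min(folds$mfe), ]
  n_pairs <- sum(strsplit(best$structure, "")[[1]] == "(")
  expect_gte(n_pairs, 28) # >= 28 of 30 planted pairs
  expect_equal(nrow(fold_locally(strrep("A", 80))), 0)
  expect_error(fold_locally("ACGU"), "at least 40")
  expect_error(fold_locally(strrep("ACGN", 20)), "invalid")
})

test_that("local fold energy agrees with a global fold of the same subsequence", {
  hp <- make_hairpin(35, 8, n_mismatches = 2, seed = 3)
  folds <- fold_locally(hp$sequence)
  best <- folds[which.min(folds$mfe), ]
  sub <- substr(hp$sequence, best$local_start + 1,
                best$local_start + nchar(best$structure))
  global <- fold_global(sub)
  expect_lt(abs(best$mfe - global$mfe), 0.5)
})

test_that("stem-loop selection enforces length and pairing bounds", {
  hp <- make_hairpin(35, 10, seed = 5) # 80 nt, 70 paired
  folds <- fold_locally(hp$sequence)
  sl <- select_stemloop(folds, hp$sequence)
  expect_false(is.null(sl))
  expect_gte(sl$length, 60)
  paired <- 1 - lengths(regmatches(sl$structure,
                                   gregexpr("\\.", sl$structure))) /
    nchar(sl$structure)
  expect_gte(paired, 0.5)
  # a 40-nt hairpin is below the minimum precursor length
  hp40 <- make_hairpin(18, 4, seed = 6) # 40 nt
  sl40 <- select_stemloop(fold_locally(hp40$sequence), hp40$sequence)
  expect_null(sl40)
  # raising min_len above the structure length rejects it
  expect_null(select_stemloop(folds, hp$sequence, min_len = 200))
})

test_that("the lowest-energy qualifying stem-loop wins", {
  folds <- tibble::tibble(
    structure = c(paste0(strrep("(", 30), strrep(".", 6), strrep(")", 30)),
                  paste0(strrep("(", 31), strrep(".", 6), strrep(")", 31))),
    mfe = c(-1, -2),
    local_start = c(0L, 70L)
  )
  weak <- make_hairpin(30, 6, seed = 8)
  strong <- make_hairpin(31, 6, gc_frac = 1, seed = 9)
  seqcat <- paste0(weak$sequence, strrep("A", 4), strong$sequence)
  sl <- select_stemloop(folds, seqcat)
  expect_equal(sl$local_start, 70L)
  expect_equal(sl$sequence, strong$sequence)
})

test_that("thermodynamic statistics follow their defining arithmetic", {
  hp <- make_hairpin(30, 6, seed = 2)
  st <- thermo_stats(hp$sequence, hp$structure)
  expect_equal(st$amfe, st$mfe / st$length * 100, tolerance = 1e-9)
  expect_equal(st$mfei, st$amfe / st$gc_percent, tolerance = 1e-9)
  # worked examples: length 100, mfe -50, GC 50% -> amfe -50, mfei -1
  expect_equal(-50 / 100 * 100, -50)
  st2 <- thermo_stats(strrep("GCAU", 25),
                      paste0(strrep("(", 48), "....", strrep(")", 48)),
                      mfe = -50)
  expect_equal(st2$amfe, -50)
  expect_equal(st2$mfei, -1)
})

test_that("AMFE is invariant under tandem duplication of the precursor", {
  hp <- make_hairpin(30, 6, seed = 12)
  st1 <- thermo_stats(hp$sequence, hp$structure, mfe = -40)
  st2 <- thermo_stats(paste0(hp$sequence, hp$sequence),
                      paste0(hp$structure, hp$structure), mfe = -80)
  expect_equal(st1$amfe, st2$amfe, tolerance = 1e-9)
  expect_equal(st1$mfei, st2$mfei, tolerance = 1e-9) # GC unchanged
})

test_that("MFEI prefilter applies a strict threshold", {
  hairpins <- tibble::tibble(mfei = c(-0.61, -0.60, -0.59, -2.0))
  kept <- mfei_prefilter(hairpins)
  expect_equal(kept$mfei, c(-0.61, -2.0))
  expect_equal(nrow(mfei_prefilter(hairpins, enabled = FALSE)), 4)
})

test_that("dinucleotide shuffles preserve all 16 dinucleotide counts and the ends", {
  hp <- make_hairpin(30, 8, seed = 21)
  shuffles <- dinucleotide_shuffle(hp$sequence, n = 10, seed = 5)
  ref <- dinuc_counts(hp$sequence)
  for (s in shuffles) {
    expect_equal(dinuc_counts(s), ref)
    expect_equal(substr(s, 1, 1), substr(hp$sequence, 1, 1))
    expect_equal(substr(s, nchar(s), nchar(s)),
                 substr(hp$sequence, nchar(hp$sequence),
                        nchar(hp$sequence)))
  }
  # shuffles do differ from the input
  expect_true(any(shuffles != hp$sequence))
  expect_error(dinucleotide_shuffle("ACG"), "too short")
})

test_that("shuffle significance separates a strong hairpin from unstructured sequence", {
  hp <- make_hairpin(45, 10, seed = 33) # 100-nt strong hairpin
  res <- shuffle_significance(hp$sequence, n = 100, seed = 17)
  expect_equal(res$empirical_p,
               (res$n_as_stable + 1) / (res$n_shuffles + 1))
  expect_lte(res$empirical_p, 0.05)
  # an unstructured sequence scores near 1
  flat <- shuffle_significance(paste(rep(c("A", "C"), 30), collapse = ""),
                               n = 20, seed = 4)
  expect_gte(flat$empirical_p, 0.5)
  expect_error(shuffle_significance(hp$sequence, n = 5), ">= 10")
})

test_that("hairpin_from_structure records a consistent arm/loop partition", {
  hp <- make_hairpin(30, 7, seed = 41)
  row <- hairpin_from_structure(hp$sequence, hp$structure)
  expect_equal(row$loop_end - row$loop_start, 7)
  expect_equal(row$length, nchar(hp$sequence))
  # arms and loop tile the precursor
  expect_equal(row$loop_start + (row$length - row$loop_end) +
                 (row$loop_end - row$loop_start), row$length)
  expect_equal(row$mfei, row$amfe / row$gc_percent, tolerance = 1e-9)
})
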