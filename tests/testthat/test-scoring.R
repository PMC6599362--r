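# Shared planted precursor for scoring tests: perfect stem, guide on the
# 5' arm. The intended structure (not a fold) drives the geometry, so
# every expected value below is computable by hand.
planted <- make_planted_locus("AGAUAUUAGUGCGGUUCAAUC", pad = 7,
                              loop_len = 10, seed = 2,
                              genomic_start = 500L)
G <- planted$guide_local_start # 7
S <- planted$star_local_start  # 40
GL <- planted$guide_len        # 21

test_that("criterion 1 applies a strict -0.8 threshold", {
  expect_true(criterion1_stability(-0.81))
  expect_false(criterion1_stability(-0.80))
  expect_true(criterion1_stability(-2.0))
  expect_false(criterion1_stability(NA_real_))
})

test_that("criterion 2 honours both the per-arm and total read thresholds", {
  ten_each <- locus_with_reads(planted, tibble::tibble(
    local_start = c(G, S), len = GL, count = c(10, 10)))
  expect_true(criterion2_reads(ten_each))
  nine_one_arm <- locus_with_reads(planted, tibble::tibble(
    local_start = c(G, S), len = GL, count = c(10, 9)))
  expect_false(criterion2_reads(nine_one_arm))
  all_99 <- locus_with_reads(planted, tibble::tibble(
    local_start = G, len = GL, count = 99))
  expect_false(criterion2_reads(all_99))
  all_100 <- locus_with_reads(planted, tibble::tibble(
    local_start = G, len = GL, count = 100))
  expect_true(criterion2_reads(all_100))
})

test_that("guide selection applies the 1/3 frequency rule with deterministic ties", {
  # 71 of 114 copies: guide selected at 62%
  locus <- locus_with_reads(planted, tibble::tibble(
    local_start = c(G, S, 2), len = c(GL, GL, 20),
    count = c(71, 27, 16)))
  g <- select_guide(locus)
  expect_equal(g$sequence, "AGAUAUUAGUGCGGUUCAAUC")
  expect_equal(g$count, 71)
  expect_equal(round_half_up(100 * g$freq), 62)
  expect_equal(g$arm, "5p")
  # 32 of 100 is below 1/3
  weak <- locus_with_reads(planted, tibble::tibble(
    local_start = c(G, S, 2, 25), len = c(GL, GL, 20, 20),
    count = c(32, 25, 23, 20)))
  expect_null(select_guide(weak))
  # exactly 1/3 qualifies
  third <- locus_with_reads(planted, tibble::tibble(
    local_start = c(G, S, 2), len = c(GL, GL, 20), count = c(33, 33, 33)))
  expect_false(is.null(select_guide(third)))
  # single unique read: frequency 100%
  solo <- locus_with_reads(planted, tibble::tibble(
    local_start = G, len = GL, count = 5))
  expect_equal(select_guide(solo)$freq, 1)
  # count ties break to the 5'-most start
  tie <- locus_with_reads(planted, tibble::tibble(
    local_start = c(S, G), len = GL, count = c(40, 40)))
  expect_equal(select_guide(tie)$local_start, G)
})

test_that("expected star position reflects the 2-nt 3' overhang geometry", {
  # perfect stem: star 5' start pairs with guide base (start + len - 3)
  expect_equal(expected_star_position(planted$structure, G, GL), S)
  # symmetric: mapping the star back recovers the guide start
  expect_equal(expected_star_position(planted$structure, S, GL), G)
  # a guide crossing the terminal loop is an error
  expect_error(expected_star_position(planted$structure, 20, 21),
               "loop")
})

test_that("star mapping extrapolates across unpaired guide ends", {
  # open the pair at the guide's mapping anchor (position G+GL-3): the
  # star position must be unchanged thanks to linear extrapolation
  st <- strsplit(planted$structure, "")[[1]]
  anchor <- G + GL - 2 # 1-based
  partner <- pair_table(planted$structure)[anchor]
  st[c(anchor, partner)] <- "."
  expect_equal(expected_star_position(paste(st, collapse = ""), G, GL), S)
})

test_that("criterion 4 counts copies starting in the guide [-3,+3] and star [-5,+5] windows", {
  # 71 at guide, 27 at star, 16 outside: 98/114 = 86%
  locus <- locus_with_reads(planted, tibble::tibble(
    local_start = c(G, S, 2), len = c(GL, GL, 20),
    count = c(71, 27, 16)))
  g <- select_guide(locus)
  expect_true(criterion4_precision(locus, g, S))
  # 75 of 100 passes, 74 of 100 fails
  at75 <- locus_with_reads(planted, tibble::tibble(
    local_start = c(G, 2), len = c(GL, 20), count = c(75, 25)))
  g75 <- select_guide(at75)
  expect_true(criterion4_precision(at75, g75, S))
  at74 <- locus_with_reads(planted, tibble::tibble(
    local_start = c(G, 2), len = c(GL, 20), count = c(74, 26)))
  expect_false(criterion4_precision(at74, select_guide(at74), S))
  # window boundaries: starts at +3 of the guide and +5 of the star count
  edges <- locus_with_reads(planted, tibble::tibble(
    local_start = c(G, G + 3, S + 5), len = c(GL, GL, GL - 5),
    count = c(60, 15, 25)))
  expect_true(criterion4_precision(edges, select_guide(edges), S))
  # one step past either window and the same copies no longer count
  past <- locus_with_reads(planted, tibble::tibble(
    local_start = c(G, G + 4, S + 6), len = c(GL, GL, GL - 6),
    count = c(60, 15, 25)))
  expect_false(criterion4_precision(past, select_guide(past), S))
})

test_that("criterion 5 needs a single read copy in the star window", {
  with_star <- locus_with_reads(planted, tibble::tibble(
    local_start = c(G, S + 5), len = c(GL, GL - 5), count = c(71, 1)))
  expect_true(criterion5_star_expressed(with_star, S))
  without <- locus_with_reads(planted, tibble::tibble(
    local_start = c(G, G + 1), len = c(GL, GL), count = c(71, 10)))
  expect_false(criterion5_star_expressed(without, S))
  beyond <- locus_with_reads(planted, tibble::tibble(
    local_start = c(G, S + 6), len = c(GL, GL - 6), count = c(71, 9)))
  expect_false(criterion5_star_expressed(beyond, S))
  expect_false(criterion5_star_expressed(with_star, NA))
})

test_that("the duplex rule accepts canonical geometry and rejects weak pairing", {
  hp <- hairpin_from_structure(planted$sequence, planted$structure,
                               start = planted$genomic_start, mfe = -40)
  guide <- tibble::tibble(sequence = planted$guide_seq,
                          local_start = G, length = GL, count = 71L,
                          freq = 0.62, arm = "5p")
  expect_true(criterion6_duplex_stability(hp, guide))
  # mostly unpaired guide: dissolve 13 of its 21 pairs
  st <- strsplit(planted$structure, "")[[1]]
  pt <- pair_table(planted$structure)
  broken <- (G + 1):(G + 13)
  st[c(broken, pt[broken])] <- "."
  hp_weak <- hairpin_from_structure(planted$sequence,
                                    paste(st, collapse = ""),
                                    start = planted$genomic_start,
                                    mfe = -10)
  expect_false(criterion6_duplex_stability(hp_weak, guide))
  # a pluggable rule overrides the default
  expect_true(criterion6_duplex_stability(hp_weak, guide,
                                          rule = function(h, g) TRUE))
})

test_that("a canonical locus reaches 6 stars and the pieces agree", {
  locus <- locus_with_reads(planted, tibble::tibble(
    local_start = c(G, S, 1), len = c(GL, GL, 20),
    count = c(71, 27, 16)))
  qs <- compute_quality_score(locus)
  expect_true(all(unlist(qs[paste0("c", 1:6)])))
  expect_equal(qs$score, 6L)
  expect_equal(qs$guide_seq, "AGAUAUUAGUGCGGUUCAAUC")
  expect_equal(qs$guide_len, 21L)
  expect_equal(qs$star_expected_start, S)
  expect_equal(qs$star_count, 27L)
  expect_equal(qs$total_reads, 114L)
  expect_equal(qs$n_unique_reads, 3L)
})

test_that("score equals the number of true criteria over all 64 combinations", {
  locus <- locus_with_reads(planted, tibble::tibble(
    local_start = c(G, S), len = GL, count = c(71, 27)))
  for (mask in 0:63) {
    bits <- as.logical(bitwAnd(mask, 2^(0:5)))
    funs <- setNames(lapply(bits, function(b) {
      force(b)
      function(locus, guide, star_pos) b
    }), paste0("c", 1:6))
    qs <- compute_quality_score(locus, criterion_funs = funs)
    expect_equal(qs$score, sum(bits))
    expect_equal(unlist(qs[paste0("c", 1:6)], use.names = FALSE), bits)
  }
})

test_that("without a guide, criteria 3-6 are forced false and the score caps at 2", {
  diffuse <- locus_with_reads(planted, tibble::tibble(
    local_start = c(2, 12, 25, 41, 50), len = 20,
    count = c(30, 30, 30, 30, 30)))
  expect_null(select_guide(diffuse))
  qs <- compute_quality_score(diffuse)
  expect_false(any(qs$c3, qs$c4, qs$c5, qs$c6))
  expect_lte(qs$score, 2L)
  # even injected criteria cannot lift c4-c6 without a guide
  always <- setNames(lapply(1:6, function(i) function(l, g, s) TRUE),
                     paste0("c", 1:6))
  qs2 <- compute_quality_score(diffuse, criterion_funs = always)
  expect_lte(qs2$score, 2L)
})

test_that("adding guide-position copies never decreases criteria 2-4", {
  base_spec <- tibble::tibble(local_start = c(G, S, 2),
                              len = c(GL, GL, 20), count = c(40, 12, 30))
  before <- compute_quality_score(locus_with_reads(planted, base_spec))
  more <- base_spec
  more$count[1] <- more$count[1] + 60
  after <- compute_quality_score(locus_with_reads(planted, more))
  expect_gte(after$c2, before$c2)
  expect_gte(after$c3, before$c3)
  expect_gte(after$c4, before$c4)
})
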