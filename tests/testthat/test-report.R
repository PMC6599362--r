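test_that("read cloud rendering has the documented geometry", {
  planted <- make_planted_locus("AGAUAUUAGUGCGGUUCAAUC", pad = 7,
                                loop_len = 10, seed = 2)
  # one 21-nt read with 5 copies at offset 3 in the precursor
  locus <- locus_with_reads(planted, tibble::tibble(
    local_start = 3, len = 21, count = 5))
  qs <- compute_quality_score(locus)
  pred <- dplyr::bind_cols(locus$hairpin, qs,
                           tibble::tibble(reads = list(locus$reads),
                                          conservation = list(tibble::tibble())))
  lines <- render_read_cloud(pred)
  expect_equal(lines[1], planted$sequence)
  expect_equal(lines[2], planted$structure)
  len <- nchar(planted$sequence)
  read_line <- lines[length(lines)]
  expect_match(read_line, " length=21 depth=5$")
  body <- sub(" length.*", "", read_line)
  expect_equal(nchar(body), len)
  expect_equal(substr(body, 1, 3), "...")
  expect_match(substr(body, 4, 24), "^[A-Z*]{21}$")
  expect_equal(substr(body, 25, len), strrep(".", len - 24))
})

test_that("the guide read is written in letters, others as asterisks", {
  fx <- canonical_locus_fixture()
  locus <- planted_locus_for_scoring(fx$planted, fx$reads)
  qs <- compute_quality_score(locus)
  pred <- dplyr::bind_cols(locus$hairpin, qs,
                           tibble::tibble(reads = list(locus$reads),
                                          conservation = list(tibble::tibble())))
  lines <- render_read_cloud(pred)
  # duplex-highlight line: bracketed guide + star spans, no sequence text
  expect_false(grepl("[A-Z*]", lines[3]))
  expect_equal(stringr::str_count(lines[3], stringr::fixed("[")), 2)
  expect_equal(nchar(lines[3]), nchar(lines[1]))
  read_lines <- grep("length=", lines, value = TRUE)
  expect_equal(length(read_lines), 7)
  depths <- as.integer(sub(".*depth=(\\d+)$", "\\1", read_lines))
  expect_equal(sum(depths), 114)
  expect_equal(sum(grepl("AGAUAUUAGUGCGGUUCAAUC", read_lines)), 1)
  expect_equal(sum(grepl("\\*", read_lines)), 6)
})

test_that("no duplex-highlight line is drawn without a guide", {
  planted <- make_planted_locus("AGAUAUUAGUGCGGUUCAAUC", pad = 7,
                                loop_len = 10, seed = 2)
  diffuse <- locus_with_reads(planted, tibble::tibble(
    local_start = c(2, 12, 25, 44), len = 18, count = c(3, 3, 3, 3)))
  qs <- compute_quality_score(diffuse)
  pred <- dplyr::bind_cols(diffuse$hairpin, qs,
                           tibble::tibble(reads = list(diffuse$reads),
                                          conservation = list(tibble::tibble())))
  lines <- render_read_cloud(pred)
  expect_false(any(grepl("\\[", lines)))
})

test_that("the summary table has the documented columns and sort orders", {
  ds <- make_dataset(n_loci = 2, length = 9000, seed = 15)
  # degrade the second locus: drop its star reads so it scores lower
  reads <- ds$reads
  second <- ds$loci[[2]]
  star_g <- second$genomic_start + second$star_local_start
  reads <- reads[!(reads$start == star_g), ]
  run <- run_pipeline(reads, ds$genome)
  p <- tidy(run)
  expect_equal(nrow(p), 2)
  expect_true(length(unique(p$score)) == 2)
  tab <- build_summary(p, sort = "position")
  expect_equal(names(tab),
               c("name", "position", "strand", "quality_score", "reads",
                 "reads_flag", "reads_distribution", "mfei", "mfei_flag",
                 "mirna_sequence", "mirna_length", "weight", "alignment"))
  expect_equal(tab$name, sort(tab$name)) # positional order here
  bq <- build_summary(p, sort = "quality")
  expect_equal(bq$quality_score, sort(bq$quality_score,
                                      decreasing = TRUE))
  expect_error(build_summary(p, sort = "reads"), "unknown sort")
  # reads-distribution is the count of satisfied criteria among 4-6
  expect_equal(tab$reads_distribution,
               as.integer(p$c4 + p$c5 + p$c6)[order(p$start)])
})

test_that("conservation flags surface as checked / double-checked", {
  ds <- make_dataset(n_loci = 1, length = 6000, seed = 1)
  guide <- ds$loci[[1]]$guide_seq
  run_dc <- run_pipeline(ds$reads, ds$genome,
                         mature_db = tibble::tibble(id = "m1", seq = guide))
  expect_equal(tidy(run_dc)$alignment, "double-checked")
  loop_seq <- substr(ds$loci[[1]]$sequence, 29, 49) # loop-spanning, off-guide
  run_ch <- run_pipeline(ds$reads, ds$genome,
                         mature_db = tibble::tibble(id = "m2",
                                                    seq = loop_seq))
  expect_equal(tidy(run_ch)$alignment, "checked")
  run_none <- run_pipeline(ds$reads, ds$genome)
  expect_equal(tidy(run_none)$alignment, "none")
})

test_that("the pipeline is deterministic and conserves read provenance", {
  ds <- make_dataset(n_loci = 1, length = 6000, seed = 8)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run1 <- run_pipeline(ds$reads, ds$genome)
  run2 <- run_pipeline(ds$reads, ds$genome)
  write_exports(run1, d1)
  write_exports(run2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # every prediction's reads are a subset of the prefiltered input
  p <- tidy(run1)
  cloud <- p$reads[[1]]
  keys <- paste(cloud$chrom, cloud$start, cloud$sequence)
  input_keys <- paste(ds$reads$chrom, ds$reads$start, ds$reads$sequence)
  expect_true(all(keys %in% input_keys))
})

test_that("an empty read set produces a valid empty run", {
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 500)))
  run <- run_pipeline(plantmir:::empty_reads(), genome)
  expect_equal(nrow(tidy(run)), 0)
  expect_equal(run$filter_report$n_input, 0)
  d <- withr::local_tempdir()
  write_exports(run, d)
  expect_equal(readLines(file.path(d, "predictions.gff3")),
               "##gff-version 3")
  g <- glance(run)
  expect_equal(g$n_predictions, 0)
})

test_that("known-miRNA loci are reported separately and excluded from discovery", {
  ds <- make_dataset(n_loci = 1, length = 6000, seed = 1)
  known <- ds$truth
  run <- run_pipeline(ds$reads, ds$genome, known_features = known)
  expect_equal(nrow(tidy(run)), 0) # all reads belong to the known locus
  expect_equal(nrow(run$known_report), 1)
  expect_equal(run$known_report$n_reads, sum(ds$reads$count))
})
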