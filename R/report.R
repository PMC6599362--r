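# Assembly of predictions, text rendering and the end-to-end driver.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the workflow with its default.
#'
#' @param mask_annotations mask reads overlapping annotation features.
#' @param max_genomic_hits multi-mapping removal threshold (reads at more
#'   loci than this are dropped).
#' @param cluster_gap,peak_floor peak calling (see [call_peaks()]).
#' @param max_distance,min_paired,max_bulges,bulge_len duplex-partner
#'   search (see [find_duplex_partner()]).
#' @param fold_margin,max_span,min_hairpin_len,max_hairpin_len,min_paired_frac
#'   hairpin folding and stem-loop compatibility.
#' @param mfei_filter,mfei_threshold optional MFEI prefilter (< -0.6).
#' @param mfei_star_threshold criterion-1 threshold (< -0.8).
#' @param min_arm_reads,min_total_reads,guide_min_freq,precision_frac
#'   read-based criteria thresholds.
#' @param guide_window,star_window criterion window half-widths.
#' @param max_edits conservation-alignment edit budget.
#' @param min_score drop predictions below this quality score.
#' @param sort summary sort order, `"position"` or `"quality"`.
#' @param shuffle_n dinucleotide shuffles per candidate (0 disables the
#'   significance test).
#' @param rng_seed seed for the shuffle test.
#' @return named list of class `mir_config`.
#' @export
pipeline_config <- function(mask_annotations = TRUE, max_genomic_hits = 5,
                            cluster_gap = 30, peak_floor = 10,
                            max_distance = 350, min_paired = 14,
                            max_bulges = 2, bulge_len = 2,
                            fold_margin = 30, max_span = 350,
                            min_hairpin_len = 60, max_hairpin_len = 350,
                            min_paired_frac = 0.5, mfei_filter = TRUE,
                            mfei_threshold = -0.6,
                            mfei_star_threshold = -0.8, min_arm_reads = 10,
                            min_total_reads = 100, guide_min_freq = 1 / 3,
                            precision_frac = 0.75, guide_window = 3,
                            star_window = 5, max_edits = 3, min_score = 0,
                            sort = "position", shuffle_n = 0,
                            rng_seed = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "mir_config"
  cfg
}

locus_name <- function(chrom, start, end, strand) {
  sprintf("%s__%d-%d_%s", chrom, start, end, strand)
}

# Collapse hairpins that describe the same locus (same strand, >= 30 bp
# overlap): the guide-arm peak and the star-arm peak of one precursor both
# rediscover it. The most stable (lowest MFE) representative wins.
dedupe_hairpins <- function(hairpins) {
  if (nrow(hairpins) < 2) return(hairpins)
  hairpins <- arrange(hairpins, .data$mfe)
  keep <- logical(nrow(hairpins))
  for (i in seq_len(nrow(hairpins))) {
    taken <- hairpins[keep, ]
    ov <- taken$chrom == hairpins$chrom[i] &
      taken$strand == hairpins$strand[i] &
      pmin(taken$end, hairpins$end[i]) -
        pmax(taken$start, hairpins$start[i]) >= 30
    keep[i] <- !any(ov)
  }
  arrange(hairpins[keep, ], .data$chrom, .data$start, .data$strand)
}

#' Run the full prediction workflow
#'
#' Prefilters the reads, discovers candidate loci, folds them into
#' stem-loop precursors, scores the six quality criteria, annotates
#' conservation and duplications, and assembles the prediction table.
#' Deterministic for fixed inputs and `rng_seed`.
#'
#' @param reads tibble of read alignments ([read_bed()]), or a BED path.
#' @param genome [Biostrings::DNAStringSet] ([read_genome()]), or a FASTA
#'   path.
#' @param mask_features annotation features to mask, or a GFF path.
#' @param known_features known precursor coordinates, or a GFF path.
#' @param mature_db known mature miRNAs ([read_mature_db()]), or a FASTA
#'   path.
#' @param config a [pipeline_config()].
#' @param verbose log per-stage record counts.
#' @return object of class `mir_run`: list with `predictions` (tibble, one
#'   row per predicted precursor with criteria, score, guide/star calls,
#'   annotations and a nested read cloud), `filter_report`,
#'   `known_report` and `config`.
#' @export
run_pipeline <- function(reads, genome, mask_features = NULL,
                         known_features = NULL, mature_db = NULL,
                         config = pipeline_config(), verbose = FALSE) {
  if (is.character(reads)) reads <- read_bed(reads)
  if (is.character(genome)) genome <- read_genome(genome)
  if (is.character(mask_features)) {
    mask_features <- read_gff(mask_features,
                              c("CDS", "tRNA", "rRNA", "snoRNA"))
  }
  if (is.character(known_features)) {
    known_features <- read_gff(known_features,
                               c("miRNA_primary_transcript"))
  }
  if (is.character(mature_db)) mature_db <- read_mature_db(mature_db)
  if (is.null(genome)) abort("a genome is required")
  reads <- validate_reads(reads)
  pre <- prefilter_reads(reads, mask_features = mask_features,
                         known_features = known_features,
                         max_hits = config$max_genomic_hits,
                         mask_annotations = config$mask_annotations)
  msg_stage(verbose, "prefilter: %d/%d read records retained",
            pre$report$n_retained, pre$report$n_input)
  cands <- discover_loci(pre$retained, genome,
                         cluster_gap = config$cluster_gap,
                         peak_floor = config$peak_floor,
                         max_distance = config$max_distance,
                         min_paired = config$min_paired,
                         max_bulges = config$max_bulges,
                         bulge_len = config$bulge_len)
  msg_stage(verbose, "locus discovery: %d candidate loci", nrow(cands))
  hairpins <- purrr::map(seq_len(nrow(cands)), function(i) {
    fold_candidate(cands[i, ], genome, margin = config$fold_margin,
                   max_span = config$max_span,
                   min_len = config$min_hairpin_len,
                   max_len = config$max_hairpin_len,
                   min_paired_frac = config$min_paired_frac)
  })
  hairpins <- bind_rows(purrr::compact(hairpins))
  if (nrow(hairpins)) {
    hairpins <- dedupe_hairpins(hairpins)
    hairpins <- mfei_prefilter(hairpins, threshold = config$mfei_threshold,
                               enabled = config$mfei_filter)
  }
  msg_stage(verbose, "hairpin: %d stem-loop precursors", nrow(hairpins))
  preds <- purrr::map(seq_len(nrow(hairpins)), function(i) {
    hp <- hairpins[i, ]
    locus <- read_cloud_locus(hp, pre$retained)
    if (!nrow(locus$reads)) return(NULL)
    qs <- compute_quality_score(
      locus, mfei_star_threshold = config$mfei_star_threshold,
      min_arm_reads = config$min_arm_reads,
      min_total_reads = config$min_total_reads,
      guide_min_freq = config$guide_min_freq,
      precision_frac = config$precision_frac,
      guide_window = config$guide_window,
      star_window = config$star_window
    )
    dplyr::bind_cols(hp, qs, tibble(reads = list(locus$reads)))
  })
  preds <- bind_rows(purrr::compact(preds))
  if (nrow(preds)) {
    preds$name <- locus_name(preds$chrom, preds$start, preds$end,
                             preds$strand)
    preds <- filter(preds, .data$score >= config$min_score)
  }
  msg_stage(verbose, "scoring: %d predictions at min_score %d",
            nrow(preds), config$min_score)
  if (nrow(preds)) {
    ann <- purrr::map(seq_len(nrow(preds)), function(i) {
      p <- preds[i, ]
      gi <- if (!is.na(p$guide_seq)) {
        c(p$guide_local_start, p$guide_local_start + p$guide_len)
      } else NULL
      cons <- align_to_known_matures(p$sequence, mature_db,
                                     max_edits = config$max_edits,
                                     guide_interval = gi)
      if (!is.na(p$guide_seq)) {
        dup <- duplication_check(
          p$guide_seq, genome, predictions = preds,
          self_interval = list(chrom = p$chrom, start = p$start,
                               end = p$end)
        )
        weight <- compute_weight(p$guide_count,
                                 dup$n_genomic_occurrences)
      } else {
        dup <- tibble(n_genomic_occurrences = NA_integer_,
                      other_loci = list(tibble()),
                      overlaps_other_prediction = FALSE)
        weight <- NA_real_
      }
      alignment <- if (!nrow(cons)) "none" else
        if (any(cons$overlaps_guide)) "double-checked" else "checked"
      tibble(conservation = list(cons),
             n_genomic_occurrences = dup$n_genomic_occurrences,
             overlaps_other_prediction = dup$overlaps_other_prediction,
             weight = weight, alignment = alignment)
    }) |> bind_rows()
    preds <- dplyr::bind_cols(preds, ann)
    if (config$shuffle_n >= 10) {
      preds$shuffle_p <- purrr::map_dbl(seq_len(nrow(preds)), function(i) {
        shuffle_significance(preds$sequence[i], n = config$shuffle_n,
                             seed = config$rng_seed,
                             mfe = preds$mfe[i])$empirical_p
      })
    }
    preds <- arrange(preds, .data$chrom, .data$start, .data$strand) |>
      select("name", dplyr::everything())
  } else {
    preds <- empty_predictions()
  }
  msg_stage(verbose, "report: %d final predictions", nrow(preds))
  structure(
    list(predictions = preds, filter_report = pre$report,
         known_report = pre$known_report, config = config),
    class = "mir_run"
  )
}

empty_predictions <- function() {
  tibble(
    name = character(), chrom = character(), strand = character(),
    start = integer(), end = integer(), sequence = character(),
    structure = character(), mfe = numeric(), amfe = numeric(),
    mfei = numeric(), gc_percent = numeric(), length = integer(),
    loop_start = integer(), loop_end = integer(),
    c1 = logical(), c2 = logical(), c3 = logical(), c4 = logical(),
    c5 = logical(), c6 = logical(), score = integer(),
    guide_defined = logical(), guide_seq = character(),
    guide_local_start = integer(), guide_len = integer(),
    guide_arm = character(), guide_count = integer(),
    guide_freq = numeric(), star_expected_start = integer(),
    star_seq = character(), star_count = integer(),
    total_reads = integer(), n_unique_reads = integer(),
    reads = list(), conservation = list(),
    n_genomic_occurrences = integer(),
    overlaps_other_prediction = logical(), weight = numeric(),
    alignment = character()
  )
}

#' Summary table of predictions
#'
#' One row per predicted precursor with the headline columns: locus name
#' and position, read support (flagged when criterion 2 holds), the
#' reads-distribution score (number of satisfied criteria among 4-6),
#' MFEI (flagged when below -0.8), the guide miRNA and its length, the
#' weight, and the conservation-alignment flag.
#'
#' @param predictions predictions tibble (or a `mir_run`).
#' @param sort `"position"` (default) or `"quality"` (descending score,
#'   ties by position).
#' @return summary tibble.
#' @export
build_summary <- function(predictions, sort = "position") {
  if (inherits(predictions, "mir_run")) {
    predictions <- predictions$predictions
  }
  if (!sort %in% c("position", "quality")) {
    abort(paste0("unknown sort key: ", sort))
  }
  tab <- tibble(
    name = predictions$name,
    position = sprintf("%s:%d-%d", predictions$chrom,
                       predictions$start + 1L, predictions$end),
    strand = predictions$strand,
    quality_score = predictions$score,
    reads = predictions$total_reads,
    reads_flag = predictions$c2,
    reads_distribution = as.integer(predictions$c4 + predictions$c5 +
                                      predictions$c6),
    mfei = round(predictions$mfei, 3),
    mfei_flag = predictions$c1,
    mirna_sequence = predictions$guide_seq,
    mirna_length = predictions$guide_len,
    weight = predictions$weight,
    alignment = predictions$alignment,
    chrom = predictions$chrom, start = predictions$start
  )
  tab <- if (sort == "quality") {
    arrange(tab, desc(.data$quality_score), .data$chrom, .data$start)
  } else {
    arrange(tab, .data$chrom, .data$start)
  }
  select(tab, -"chrom", -"start")
}

span_line <- function(len, intervals, fill = ".", mark = "=",
                      open = "[", close = "]") {
  chars <- rep(fill, len)
  for (iv in intervals) {
    a <- max(1L, iv[1] + 1L)
    b <- min(len, iv[2])
    if (b < a) next
    chars[a:b] <- mark
    chars[a] <- open
    chars[b] <- close
  }
  paste(chars, collapse = "")
}

#' Render the text read cloud of a prediction
#'
#' Emits the precursor sequence, its dot-bracket structure, a
#' square-bracket line highlighting the miRNA duplex (when the guide is
#' defined), the conservation-hit positions (when any), then one line per
#' unique read: asterisks spanning the read, padded with dots, annotated
#' with `length=L depth=D`. The guide read is written in letters.
#'
#' @param prediction one-row predictions tibble.
#' @return character vector of text lines.
#' @export
render_read_cloud <- function(prediction) {
  stopifnot(nrow(prediction) == 1)
  len <- nchar(prediction$sequence)
  lines <- c(prediction$sequence, prediction$structure)
  if (!is.na(prediction$guide_seq)) {
    duplex <- list(
      c(prediction$guide_local_start,
        prediction$guide_local_start + prediction$guide_len)
    )
    if (!is.na(prediction$star_expected_start)) {
      duplex <- c(duplex, list(
        c(prediction$star_expected_start,
          prediction$star_expected_start + prediction$guide_len)
      ))
    }
    lines <- c(lines, span_line(len, duplex))
  }
  cons <- prediction$conservation[[1]]
  if (!is.null(cons) && nrow(cons)) {
    ivs <- purrr::map(seq_len(nrow(cons)), function(i) {
      c(cons$local_start[i], cons$local_end[i])
    })
    lines <- c(lines, span_line(len, ivs, mark = "~", open = "~",
                                close = "~"))
  }
  reads <- prediction$reads[[1]]
  if (!is.null(reads) && nrow(reads)) {
    reads <- arrange(reads, .data$local_start, desc(.data$count))
    for (i in seq_len(nrow(reads))) {
      a <- reads$local_start[i]
      b <- reads$local_end[i]
      rl <- b - a
      a_cl <- max(0L, a)
      b_cl <- min(len, b)
      body <- if (!is.na(prediction$guide_seq) &&
                  identical(reads$sequence[i], prediction$guide_seq) &&
                  a == prediction$guide_local_start) {
        substr(reads$sequence[i], a_cl - a + 1L, b_cl - a)
      } else {
        strrep("*", b_cl - a_cl)
      }
      line <- paste0(strrep(".", a_cl), body, strrep(".", len - b_cl),
                     sprintf(" length=%d depth=%d", rl, reads$count[i]))
      lines <- c(lines, line)
    }
  }
  lines
}

#' @export
print.mir_run <- function(x, ...) {
  cat("miRNA prediction run\n")
  cat(sprintf("  reads: %d records in, %d retained (%d known-miRNA, %d masked, %d multimapped)\n",
              x$filter_report$n_input, x$filter_report$n_retained,
              x$filter_report$n_known_mirna, x$filter_report$n_masked,
              x$filter_report$n_multimap_removed))
  cat(sprintf("  predictions: %d\n", nrow(x$predictions)))
  if (nrow(x$predictions)) {
    tab <- table(factor(x$predictions$score, levels = 0:6))
    cat("  score distribution (0-6 stars):",
        paste(rev(tab), collapse = " / "), "(6 first)\n")
  }
  invisible(x)
}

#' Tidy a prediction run
#'
#' @param x a `mir_run`.
#' @param ... unused.
#' @return the predictions tibble.
#' @export
tidy.mir_run <- function(x, ...) {
  x$predictions
}

#' One-row summary of a prediction run
#'
#' @param x a `mir_run`.
#' @param ... unused.
#' @return tibble with read-filter counts and per-score prediction counts.
#' @export
glance.mir_run <- function(x, ...) {
  p <- x$predictions
  dplyr::bind_cols(
    x$filter_report,
    tibble(
      n_predictions = nrow(p),
      n_score6 = sum(p$score == 6), n_score5 = sum(p$score == 5),
      n_score4 = sum(p$score == 4), n_score3 = sum(p$score == 3),
      n_with_guide = sum(p$guide_defined),
      n_conserved = sum(p$alignment != "none")
    )
  )
}

#' Write every export format for a run
#'
#' @param run a `mir_run`.
#' @param dir output directory (created if needed).
#' @param sort summary sort order.
#' @return `dir`, invisibly.
#' @export
write_exports <- function(run, dir, sort = "position") {
  stopifnot(inherits(run, "mir_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- run$predictions
  write_summary_csv(p, file.path(dir, "summary.csv"), sort = sort)
  write_gff(p, file.path(dir, "predictions.gff3"))
  write_dotbracket(p, file.path(dir, "precursors.dbn"))
  write_org(p, file.path(dir, "report.org"))
  clouds <- unlist(purrr::map(seq_len(nrow(p)), function(i) {
    c(paste0(">", p$name[i]), render_read_cloud(p[i, ]), "")
  }))
  writeLines(if (is.null(clouds)) character() else clouds,
             file.path(dir, "read_clouds.txt"))
  invisible(dir)
}
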