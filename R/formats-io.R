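# External formats. Internal coordinates are uniformly 0-based half-open;
# the 1-based inclusive convention of GFF3 exists only inside this file.

#' Read a small-RNA alignment BED file
#'
#' The expected dialect is BED6 with the read sequence in the name column
#' and the collapsed copy count in the score column, plus an optional 7th
#' column giving the number of loci the read sequence maps to genome-wide:
#' `chrom start end sequence count strand [n_hits]`.
#'
#' @param path path to the BED file.
#' @return tibble of read alignments with columns `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `sequence` (read orientation, RNA
#'   alphabet), `count`, `n_hits`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_reads())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6)) {
    abort(sprintf("malformed BED line %d: expected >= 6 tab-separated columns",
                  which(nf < 6)[1]))
  }
  col <- function(i) vapply(fields, `[`, character(1), i)
  reads <- tibble(
    chrom = col(1),
    start = suppressWarnings(as.integer(col(2))),
    end = suppressWarnings(as.integer(col(3))),
    sequence = as_rna(col(4)),
    count = suppressWarnings(as.integer(col(5))),
    strand = col(6),
    n_hits = suppressWarnings(as.integer(vapply(fields, function(f) {
      if (length(f) >= 7) f[7] else "1"
    }, character(1))))
  )
  bad <- which(is.na(reads$start) | is.na(reads$end) | is.na(reads$count) |
                 is.na(reads$n_hits))
  if (length(bad)) abort(sprintf("malformed BED line %d: non-numeric field",
                                 bad[1]))
  if (any(reads$count <= 0)) {
    abort(sprintf("malformed BED line %d: count must be positive",
                  which(reads$count <= 0)[1]))
  }
  bad <- which(reads$end - reads$start != nchar(reads$sequence))
  if (length(bad)) {
    abort(sprintf("malformed BED line %d: interval length != sequence length",
                  bad[1]))
  }
  validate_reads(select(reads, "chrom", "start", "end", "strand",
                        "sequence", "count", "n_hits"))
}

#' Write read alignments as BED6+1
#'
#' @param reads tibble of read alignments.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(reads, path) {
  reads <- validate_reads(reads)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%d",
                   reads$chrom, reads$start, reads$end, reads$sequence,
                   reads$count, reads$strand, reads$n_hits)
  writeLines(lines, path)
  invisible(path)
}

#' Convert SAM/BAM alignments to collapsed read records
#'
#' Identical reads at the same position are collapsed with summed counts,
#' and each read sequence is annotated with the number of distinct loci it
#' aligns to within the file (`n_hits`). Minus-strand alignments are
#' reverse-complemented back to read orientation.
#'
#' @param path SAM or BAM file of mapped small-RNA reads.
#' @return tibble of read alignments (see [read_bed()]).
#' @export
sam_to_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  }
  rec <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("rname", "pos", "strand", "seq", "flag"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
    )
  )[[1]]
  if (!length(rec$pos) || all(is.na(rec$pos))) {
    warn("no mapped reads in alignment file")
    return(empty_reads())
  }
  keep <- !is.na(rec$pos)
  seqs <- as.character(rec$seq[keep])
  strand <- as.character(rec$strand[keep])
  minus <- strand == "-"
  if (any(minus)) {
    seqs[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[minus])))
  }
  reads <- tibble(
    chrom = as.character(rec$rname[keep]),
    start = as.integer(rec$pos[keep]) - 1L,
    strand = strand,
    sequence = as_rna(seqs)
  )
  reads$end <- reads$start + nchar(reads$sequence)
  collapsed <- reads |>
    group_by(.data$chrom, .data$start, .data$end, .data$strand,
             .data$sequence) |>
    summarise(count = dplyr::n(), .groups = "drop")
  hits <- collapsed |>
    dplyr::distinct(.data$chrom, .data$start, .data$strand, .data$sequence) |>
    dplyr::count(.data$sequence, name = "n_hits")
  out <- left_join(collapsed, hits, by = "sequence") |>
    select("chrom", "start", "end", "strand", "sequence", "count", "n_hits")
  validate_reads(order_reads(out))
}

#' Read genome annotation features from GFF3
#'
#' @param path GFF3 file (1-based inclusive coordinates on disk).
#' @param feature_types character vector of feature types to keep
#'   (e.g. `c("CDS", "tRNA")`); empty keeps everything.
#' @param strict error on unparsable lines instead of skipping them.
#' @return tibble with columns `chrom`, `start`, `end` (0-based half-open),
#'   `strand` (`+`, `-` or `.`), `type`, `id`.
#' @export
read_gff <- function(path, feature_types = character(), strict = FALSE) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) {
      if (strict) abort(paste0("failed to parse GFF: ", conditionMessage(e)))
      warn(paste0("tolerant GFF parse fell back to manual reader: ",
                  conditionMessage(e)))
      NULL
    }
  )
  if (is.null(gr)) return(read_gff_manual(path, feature_types))
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_
  )
  out$strand[out$strand == "*"] <- "."
  if (length(feature_types)) out <- filter(out, .data$type %in% feature_types)
  out
}

# Line-tolerant fallback used when rtracklayer rejects the whole file.
read_gff_manual <- function(path, feature_types = character()) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 8
  if (any(!ok)) warn(sprintf("skipped %d unparsable GFF lines", sum(!ok)))
  fields <- fields[ok]
  if (!length(fields)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), type = character(), id = character()))
  }
  col <- function(i) vapply(fields, `[`, character(1), i)
  out <- tibble(
    chrom = col(1), type = col(3),
    start = as.integer(col(4)) - 1L, end = as.integer(col(5)),
    strand = col(7),
    id = vapply(fields, function(f) {
      if (length(f) >= 9 && grepl("ID=", f[9])) {
        sub(".*ID=([^;]+).*", "\\1", f[9])
      } else NA_character_
    }, character(1))
  ) |> select("chrom", "start", "end", "strand", "type", "id")
  if (length(feature_types)) out <- filter(out, .data$type %in% feature_types)
  out
}

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return a [Biostrings::DNAStringSet] keyed by chromosome name (first
#'   whitespace-delimited token of each header).
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Read a mature-miRNA database FASTA
#'
#' Accepts the miRBase `mature.fa` dialect (RNA sequences, headers of the
#' form `id species description`).
#'
#' @param path FASTA file of mature miRNA sequences.
#' @return tibble with columns `id` and `seq` (RNA alphabet).
#' @export
read_mature_db <- function(path) {
  set <- Biostrings::readBStringSet(path)
  tibble(
    id = sub("\\s.*$", "", names(set)),
    seq = as_rna(as.character(set))
  )
}

gff_escape <- function(x) gsub("[;=\t]", "_", x)

#' Export predictions as GFF3
#'
#' Emits one `miRNA_primary_transcript` feature per predicted precursor and
#' a child `miRNA` feature for the guide when one is defined. Coordinates
#' are 1-based inclusive per GFF3.
#'
#' @param predictions finalized predictions tibble (see [run_pipeline()]).
#' @param path optional output path.
#' @return the GFF text as a character vector of lines (invisibly when
#'   `path` is given).
#' @export
write_gff <- function(predictions, path = NULL) {
  lines <- "##gff-version 3"
  if (nrow(predictions)) {
    pre <- sprintf(
      "%s\tplantmir\tmiRNA_primary_transcript\t%d\t%d\t%d\t%s\t.\tID=%s;mfei=%s",
      predictions$chrom, predictions$start + 1L, predictions$end,
      predictions$score, predictions$strand,
      gff_escape(predictions$name), formatC(predictions$mfei, format = "f",
                                            digits = 3)
    )
    lines <- c(lines, pre)
    g <- filter(predictions, !is.na(.data$guide_seq))
    if (nrow(g)) {
      gs <- ifelse(g$strand == "+",
                   g$start + g$guide_local_start,
                   g$end - g$guide_local_start - g$guide_len)
      mi <- sprintf(
        "%s\tplantmir\tmiRNA\t%d\t%d\t%d\t%s\t.\tID=%s.mature;Parent=%s;sequence=%s",
        g$chrom, gs + 1L, gs + g$guide_len, g$score, g$strand,
        gff_escape(g$name), gff_escape(g$name), g$guide_seq
      )
      lines <- c(lines, mi)
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Export the prediction summary as CSV
#'
#' Columns mirror the summary table: locus name, position, strand, read
#' counts with the criterion-2 flag, reads-distribution score (criteria
#' 4-6), MFEI with the criterion-1 flag, guide miRNA sequence and length,
#' weight, and the conservation alignment flag.
#'
#' @inheritParams write_gff
#' @param sort `"position"` (default) or `"quality"`.
#' @return CSV text lines (invisibly when `path` is given).
#' @export
write_summary_csv <- function(predictions, path = NULL, sort = "position") {
  tab <- build_summary(predictions, sort = sort)
  txt <- character(nrow(tab) + 1)
  con <- textConnection("txt", open = "w", local = TRUE)
  utils::write.csv(tab, con, row.names = FALSE)
  close(con)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Export precursors in dot-bracket notation
#'
#' For each prediction: a FASTA header, the precursor sequence and its
#' dot-bracket structure annotated with the free energy.
#'
#' @inheritParams write_gff
#' @return text lines (invisibly when `path` is given).
#' @export
write_dotbracket <- function(predictions, path = NULL) {
  lines <- character()
  if (nrow(predictions)) {
    lines <- as.vector(rbind(
      paste0(">", predictions$name),
      predictions$sequence,
      sprintf("%s (%.2f)", predictions$structure, predictions$mfe)
    ))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Export a plain-text report in ORG-mode
#'
#' One top-level heading per prediction with its scores, annotations and
#' read cloud.
#'
#' @inheritParams write_gff
#' @return text lines (invisibly when `path` is given).
#' @export
write_org <- function(predictions, path = NULL) {
  lines <- c("#+TITLE: miRNA predictions",
             sprintf("#+PREDICTIONS: %d", nrow(predictions)))
  for (i in seq_len(nrow(predictions))) {
    p <- predictions[i, ]
    lines <- c(
      lines,
      paste0("* ", p$name),
      sprintf("  - position :: %s:%d-%d (%s)", p$chrom, p$start + 1L, p$end,
              p$strand),
      sprintf("  - quality score :: %d/6", p$score),
      sprintf("  - criteria :: %s",
              paste(ifelse(unlist(p[paste0("c", 1:6)]), "yes", "no"),
                    collapse = " ")),
      sprintf("  - mfe/amfe/mfei :: %.2f / %.2f / %.3f", p$mfe, p$amfe,
              p$mfei),
      sprintf("  - reads :: %d (%d unique)", p$total_reads, p$n_unique_reads),
      if (!is.na(p$guide_seq)) {
        c(sprintf("  - guide miRNA :: %s (%d nt, %d reads)", p$guide_seq,
                  p$guide_len, p$guide_count),
          sprintf("  - weight :: %.2f", p$weight))
      },
      sprintf("  - alignment :: %s", p$alignment),
      "  #+BEGIN_EXAMPLE",
      paste0("  ", render_read_cloud(p)),
      "  #+END_EXAMPLE"
    )
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
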