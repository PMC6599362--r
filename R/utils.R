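#' Round half away from zero
#'
#' Base R's `round()` rounds halves to even; report percentages use
#' conventional half-up rounding (62.28 -> 62, 62.5 -> 63).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# DNA -> RNA uppercase; used at every sequence entry point so the whole
# pipeline works on the {A,C,G,U} alphabet.
as_rna <- function(x) {
  chartr("Tt", "Uu", toupper(x))
}

as_dna <- function(x) {
  chartr("Uu", "Tt", toupper(x))
}

check_rna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    abort(sprintf("invalid nucleotide in %s: %s", what,
                  substr(x[bad][1], 1, 40)))
  }
  invisible(x)
}

# Reverse complement on the RNA alphabet, plain character in/out.
revcomp_rna <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGU", "UGCA", s)
    paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

gc_percent_of <- function(seq) {
  n <- nchar(seq)
  gc <- nchar(gsub("[^GC]", "", seq))
  100 * gc / n
}

# Empty reads tibble with the canonical column set (ReadAlignment).
empty_reads <- function() {
  tibble(chrom = character(), start = integer(), end = integer(),
         strand = character(), sequence = character(),
         count = integer(), n_hits = integer())
}

validate_reads <- function(reads, require_hits = FALSE) {
  needed <- c("chrom", "start", "end", "strand", "sequence", "count")
  miss <- setdiff(needed, names(reads))
  if (length(miss)) {
    abort(paste0("reads is missing columns: ", paste(miss, collapse = ", ")))
  }
  if (!"n_hits" %in% names(reads)) {
    if (require_hits) abort("reads must carry an n_hits column")
    reads$n_hits <- 1L
  }
  bad <- which(reads$end <= reads$start |
                 (reads$end - reads$start) != nchar(reads$sequence))
  if (length(bad)) {
    abort(sprintf("read %d: interval [%d,%d) inconsistent with sequence length %d",
                  bad[1], reads$start[bad[1]], reads$end[bad[1]],
                  nchar(reads$sequence[bad[1]])))
  }
  if (any(reads$count < 1L)) abort("read counts must be >= 1")
  if (any(reads$n_hits < 1L)) abort("n_hits must be >= 1")
  if (!all(reads$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  reads
}

# Genomic order used by every stage so outputs are reproducibly sorted.
order_reads <- function(reads) {
  arrange(reads, .data$chrom, .data$start, .data$end, .data$strand,
          .data$sequence)
}

reads_to_granges <- function(reads) {
  GenomicRanges::GRanges(
    seqnames = reads$chrom,
    ranges = IRanges::IRanges(start = reads$start + 1L, end = reads$end),
    strand = reads$strand
  )
}

features_to_granges <- function(features) {
  strand <- features$strand
  strand[!strand %in% c("+", "-")] <- "*"
  GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = strand
  )
}

# Extract [start, end) (0-based half-open) from a genome; minus strand
# returns the reverse complement, i.e. the expressed 5'->3' sequence.
extract_genome <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) abort(paste0("unknown chromosome: ", chrom))
  len <- Biostrings::width(genome[chrom])
  if (start < 0 || end > len || start >= end) {
    abort(sprintf("extraction [%d,%d) out of bounds for %s (length %d)",
                  start, end, chrom, len))
  }
  s <- Biostrings::subseq(genome[[chrom]], start = start + 1L, end = end)
  if (identical(strand, "-")) s <- Biostrings::reverseComplement(s)
  as_rna(as.character(s))
}

msg_stage <- function(verbose, ...) {
  if (isTRUE(verbose)) message(sprintf(...))
  invisible(NULL)
}
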