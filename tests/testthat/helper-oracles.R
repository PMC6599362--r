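# Independent brute-force oracles, kept free of the package's C++ code
# paths: the DP implementations are checked against these on small inputs.

oracle_legal_pair <- function(x, y) {
  paste0(x, y) %in% c("CG", "GC", "AU", "UA", "GU", "UG")
}

# Exhaustive enumeration of alignments of a against reverse(b) with free
# end gaps and at most max_bulges internal bulges of <= bulge_len nt,
# maximizing the number of legal pairs. Exponential; inputs must be tiny.
oracle_pairing <- function(a, b, max_bulges = 2, bulge_len = 2) {
  av <- strsplit(a, "")[[1]]
  cv <- rev(strsplit(b, "")[[1]])
  n <- length(av)
  m <- length(cv)
  rec <- function(i, j, g, inside) {
    best <- 0
    if (i <= n && j <= m) {
      if (!inside) {
        best <- max(best, rec(i + 1, j, g, FALSE), rec(i, j + 1, g, FALSE))
      }
      best <- max(best, oracle_legal_pair(av[i], cv[j]) +
                    rec(i + 1, j + 1, g, TRUE))
      if (inside && g < max_bulges) {
        for (k in seq_len(bulge_len)) {
          if (i + k <= n && j <= m) {
            best <- max(best, oracle_legal_pair(av[i + k], cv[j]) +
                          rec(i + k + 1, j + 1, g + 1, TRUE))
          }
          if (i <= n && j + k <= m) {
            best <- max(best, oracle_legal_pair(av[i], cv[j + k]) +
                          rec(i + 1, j + k + 1, g + 1, TRUE))
          }
        }
      }
    }
    best
  }
  rec(1, 1, 0, FALSE)
}

# Brute-force semiglobal edit distance (mismatches + indels, no two
# adjacent indel columns) of a pattern against any substring of text.
oracle_edit_min <- function(pattern, text) {
  pv <- strsplit(pattern, "")[[1]]
  tv <- strsplit(text, "")[[1]]
  m <- length(pv)
  n <- length(tv)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, last_indel) {
    if (i > m) return(0)
    key <- paste(i, j, last_indel)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- Inf
    if (j <= n) {
      best <- min(best, (pv[i] != tv[j]) + rec(i + 1, j + 1, FALSE))
      if (!last_indel) best <- min(best, 1 + rec(i, j + 1, TRUE))
    }
    if (!last_indel) best <- min(best, 1 + rec(i + 1, j, TRUE))
    memo[[key]] <- best
    best
  }
  # states are suffix-determined, so the memo is shared across starts
  min(vapply(1:(n + 1), function(j0) rec(1, j0, FALSE), numeric(1)))
}

random_rna <- function(n, seed = NULL) {
  f <- function() paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                        collapse = "")
  if (is.null(seed)) f() else withr::with_seed(seed, f())
}

dinuc_counts <- function(s) {
  v <- strsplit(s, "")[[1]]
  table(factor(paste0(head(v, -1), tail(v, -1)),
               levels = as.vector(outer(c("A", "C", "G", "U"),
                                        c("A", "C", "G", "U"), paste0))))
}

# A scoring-ready locus from a planted fixture: hairpin record built from
# the intended (planted) structure plus the read cloud.
planted_locus_for_scoring <- function(planted, reads) {
  hp <- hairpin_from_structure(planted$sequence, planted$structure,
                               chrom = planted$chrom,
                               start = planted$genomic_start,
                               strand = planted$strand)
  read_cloud_locus(hp, reads)
}

# Minimal locus with reads placed at explicit local offsets on a planted
# precursor; `spec` is a tibble with local_start, len, count.
locus_with_reads <- function(planted, spec) {
  reads <- dplyr::bind_rows(lapply(seq_len(nrow(spec)), function(i) {
    ls <- spec$local_start[i]
    len <- spec$len[i]
    tibble::tibble(
      chrom = planted$chrom,
      start = planted$genomic_start + ls,
      end = planted$genomic_start + ls + len,
      strand = "+",
      sequence = substr(planted$sequence, ls + 1, ls + len),
      count = as.integer(spec$count[i]),
      n_hits = 1L
    )
  }))
  planted_locus_for_scoring(planted, reads)
}

write_sam_fixture <- function(path, records,
                              sq = c("@HD\tVN:1.6\tSO:coordinate",
                                     "@SQ\tSN:chr1\tLN:100000")) {
  writeLines(c(sq, records), path)
  path
}

sam_record <- function(qname, flag, chrom, pos1, seq) {
  sprintf("%s\t%d\t%s\t%d\t42\t%dM\t*\t0\t0\t%s\t%s", qname, flag, chrom,
          pos1, nchar(seq), seq, strrep("I", nchar(seq)))
}
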