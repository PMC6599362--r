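# Wrappers around the ViennaRNA command-line programs. All folding and
# energy evaluation in the package goes through these three entry points,
# so the nearest-neighbor model is the stock Matthews-Turner parameter set.

vienna_binary <- function(name) {
  path <- Sys.which(name)
  if (!nzchar(path)) {
    abort(sprintf("ViennaRNA program '%s' not found on the PATH", name))
  }
  path
}

parse_energy <- function(x) {
  as.numeric(gsub("[()\\s]", "", x, perl = TRUE))
}

#' Locally stable secondary structures (RNALfold)
#'
#' Runs RNALfold on one RNA sequence and returns every locally stable
#' structure whose span does not exceed `max_span`.
#'
#' @param sequence RNA string (A/C/G/U; T accepted and converted).
#' @param max_span maximum base-pair span in nt (RNALfold `-L`).
#' @return tibble with columns `structure`, `mfe` (kcal/mol) and
#'   `local_start` (0-based offset of the structure in `sequence`).
#' @export
fold_locally <- function(sequence, max_span = 350) {
  sequence <- as_rna(sequence)
  check_rna(sequence)
  if (nchar(sequence) < 40) abort("sequence must be at least 40 nt")
  out <- system2(vienna_binary("RNALfold"),
                 args = c("-L", as.character(max_span)),
                 input = sequence, stdout = TRUE, stderr = FALSE)
  hits <- grep("^[.()]+ ", out, value = TRUE)
  if (!length(hits)) {
    return(tibble(structure = character(), mfe = numeric(),
                  local_start = integer()))
  }
  m <- regmatches(hits, regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)\\s+(\\d+)",
                                hits))
  ok <- lengths(m) == 4
  m <- m[ok]
  tibble(
    structure = vapply(m, `[`, character(1), 2),
    mfe = as.numeric(vapply(m, `[`, character(1), 3)),
    local_start = as.integer(vapply(m, `[`, character(1), 4)) - 1L
  )
}

#' Global minimum-free-energy fold (RNAfold)
#'
#' Folds each sequence globally and returns its MFE structure and energy.
#' Sequences are folded in a single RNAfold process.
#'
#' @param sequences character vector of RNA strings.
#' @return tibble with columns `sequence`, `structure`, `mfe`.
#' @export
fold_global <- function(sequences) {
  sequences <- as_rna(sequences)
  check_rna(sequences)
  if (!length(sequences)) {
    return(tibble(sequence = character(), structure = character(),
                  mfe = numeric()))
  }
  input <- paste0(">s", seq_along(sequences), "\n", sequences, collapse = "\n")
  out <- system2(vienna_binary("RNAfold"), args = c("--noPS"),
                 input = input, stdout = TRUE, stderr = FALSE)
  struct_lines <- grep("^[.()]+\\s+\\(", out, value = TRUE)
  if (length(struct_lines) != length(sequences)) {
    abort("RNAfold returned an unexpected number of records")
  }
  m <- regmatches(struct_lines,
                  regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)", struct_lines))
  tibble(
    sequence = sequences,
    structure = vapply(m, `[`, character(1), 2),
    mfe = as.numeric(vapply(m, `[`, character(1), 3))
  )
}

#' Free energy of a given structure (RNAeval)
#'
#' Evaluates sequence/structure pairs under the nearest-neighbor energy
#' model. Vectorised; one RNAeval process for all pairs.
#'
#' @param sequences character vector of RNA strings.
#' @param structures matching dot-bracket strings.
#' @return numeric vector of free energies in kcal/mol.
#' @export
eval_energy <- function(sequences, structures) {
  sequences <- as_rna(sequences)
  check_rna(sequences)
  stopifnot(length(sequences) == length(structures),
            all(nchar(sequences) == nchar(structures)))
  if (!length(sequences)) return(numeric())
  input <- paste0(">s", seq_along(sequences), "\n", sequences, "\n",
                  structures, collapse = "\n")
  out <- system2(vienna_binary("RNAeval"), input = input,
                 stdout = TRUE, stderr = FALSE)
  vals <- grep("^[.()]+\\s+\\(", out, value = TRUE)
  if (length(vals) != length(sequences)) {
    abort("RNAeval returned an unexpected number of records")
  }
  m <- regmatches(vals, regexec("\\(\\s*(-?[0-9.]+)\\)\\s*$", vals))
  as.numeric(vapply(m, `[`, character(1), 2))
}
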