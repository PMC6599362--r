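# Dot-bracket structure utilities: pair tables, stem-loop component
# extraction, arm/loop partition.

#' Pair table of a dot-bracket structure
#'
#' @param structure dot-bracket string.
#' @return integer vector `pt` with `pt[i]` the 1-based partner of position
#'   `i`, or `NA` when unpaired.
#' @export
pair_table <- function(structure) {
  chars <- strsplit(structure, "")[[1]]
  if (!all(chars %in% c("(", ")", "."))) {
    abort("structure must contain only '(', ')' and '.'")
  }
  pt <- rep(NA_integer_, length(chars))
  stack <- integer()
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack)) abort("unbalanced dot-bracket structure")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack)) abort("unbalanced dot-bracket structure")
  pt
}

# Base pairs (i < j) with parent/child nesting relations.
structure_pairs <- function(structure) {
  chars <- strsplit(structure, "")[[1]]
  stack <- integer()
  pairs_i <- integer()
  pairs_j <- integer()
  parent <- integer()
  open_pair <- integer() # pair id currently open at each stack depth
  cur_parent <- 0L
  id <- 0L
  pair_of_open <- integer()
  for (k in seq_along(chars)) {
    if (chars[k] == "(") {
      stack <- c(stack, k)
    } else if (chars[k] == ")") {
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      id <- id + 1L
      pairs_i[id] <- i
      pairs_j[id] <- k
      parent[id] <- NA_integer_ # fill below
    }
  }
  if (!id) {
    return(tibble(i = integer(), j = integer(), parent = integer(),
                  n_children = integer()))
  }
  ord <- order(pairs_i)
  pairs <- tibble(i = pairs_i[ord], j = pairs_j[ord])
  # parent = smallest enclosing pair
  pairs$parent <- vapply(seq_len(nrow(pairs)), function(k) {
    enclosing <- which(pairs$i < pairs$i[k] & pairs$j > pairs$j[k])
    if (!length(enclosing)) return(NA_integer_)
    enclosing[which.max(pairs$i[enclosing])]
  }, integer(1))
  # direct children = pairs whose parent is k and which are not stacked
  # continuations; here every nested pair counts, so a helix is a chain of
  # single-child pairs.
  pairs$n_children <- vapply(seq_len(nrow(pairs)), function(k) {
    sum(pairs$parent == k, na.rm = TRUE)
  }, integer(1))
  pairs
}

#' Extract single stem-loop components of a structure
#'
#' Multibranch structures are dissolved into their single-stem components:
#' for each terminal (hairpin) loop the maximal enclosing run of pairs with
#' no branching is returned as one component.
#'
#' @param structure dot-bracket string.
#' @return tibble with one row per component: `start`, `end` (1-based
#'   inclusive positions of the outermost pair), `n_pairs`.
#' @export
stemloop_components <- function(structure) {
  pairs <- structure_pairs(structure)
  if (!nrow(pairs)) {
    return(tibble(start = integer(), end = integer(), n_pairs = integer()))
  }
  terminal <- which(pairs$n_children == 0)
  comp <- purrr::map(terminal, function(k) {
    n_pairs <- 1L
    while (!is.na(pairs$parent[k]) &&
           pairs$n_children[pairs$parent[k]] == 1L) {
      k <- pairs$parent[k]
      n_pairs <- n_pairs + 1L
    }
    tibble(start = pairs$i[k], end = pairs$j[k], n_pairs = n_pairs)
  })
  bind_rows(comp)
}

# Loop/arm partition of a single-loop structure: the loop is the unpaired
# run between the last "(" and the first ")". Returns 0-based half-open
# local intervals tiling [0, len).
hairpin_partition <- function(structure) {
  chars <- strsplit(structure, "")[[1]]
  opens <- which(chars == "(")
  closes <- which(chars == ")")
  if (!length(opens) || !length(closes)) abort("structure has no stem")
  loop_start <- max(opens) # 0-based: position after last "("
  loop_end <- min(closes) - 1L # 0-based: position of first ")" exclusive
  list(arm5 = c(0L, loop_start), loop = c(loop_start, loop_end),
       arm3 = c(loop_end, length(chars)))
}

is_single_loop <- function(structure) {
  # exactly one "(...)" -> ")" transition
  runs <- rle(strsplit(gsub("\\.", "", structure), "")[[1]])
  sum(runs$values == "(") == 1 && sum(runs$values == ")") == 1 &&
    length(runs$values) == 2
}
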