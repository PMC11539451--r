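#' RNA secondary structures
#'
#' A secondary structure over one or two ordered strands is a set of base
#' pairs `(i, j)`, `i < j`, in 0-based coordinates over the concatenation of
#' the strands. Valid structures have each position in at most one pair, no
#' pseudoknots (pairs are non-crossing), only A-U / G-C / G-U pairs, hairpin
#' loops of at least 3 unpaired residues (loops containing the nick between
#' two strands are exempt), and, for two-strand complexes, at least one
#' inter-strand pair.
#'
#' @param pairs Integer matrix with two columns (`i`, `j`), 0-based.
#' @param lengths Integer vector of strand lengths (1 or 2 strands).
#' @return An object of class `rna_structure`.
#' @export
rna_structure <- function(pairs, lengths) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  lengths <- as.integer(lengths)
  stopifnot(length(lengths) %in% 1:2, all(lengths > 0))
  if (nrow(pairs) > 0) {
    swap <- pairs[, 1] > pairs[, 2]
    pairs[swap, ] <- pairs[swap, 2:1]
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  }
  structure(
    list(pairs = pairs, lengths = lengths, dot_bracket = pairs_to_db(pairs, lengths)),
    class = "rna_structure"
  )
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("<rna_structure> ", x$dot_bracket, "\n", sep = "")
  invisible(x)
}

#' Convert a pair list to dot-bracket notation
#'
#' Strands in a dimer are separated by `&`.
#'
#' @param pairs Two-column integer matrix of 0-based pairs.
#' @param lengths Strand lengths.
#' @return Dot-bracket string.
#' @export
pairs_to_db <- function(pairs, lengths) {
  n <- sum(lengths)
  db <- rep(".", n)
  if (NROW(pairs) > 0) {
    db[pairs[, 1] + 1] <- "("
    db[pairs[, 2] + 1] <- ")"
  }
  if (length(lengths) == 2) {
    db <- append(db, "&", after = lengths[1])
  }
  paste(db, collapse = "")
}

#' Parse dot-bracket notation into an `rna_structure`
#'
#' @param db Dot-bracket string; `&` separates the strands of a dimer.
#' @return An `rna_structure`.
#' @examples
#' db_to_structure("((((....))))")
#' @export
db_to_structure <- function(db) {
  stopifnot(is.character(db), length(db) == 1)
  parts <- strsplit(db, "&", fixed = TRUE)[[1]]
  lengths <- nchar(parts)
  chars <- seq_chars(paste(parts, collapse = ""))
  if (!all(chars %in% c(".", "(", ")"))) {
    stop("dot-bracket may contain only '.', '(', ')' and '&'", call. = FALSE)
  }
  open <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  for (p in seq_along(chars)) {
    if (chars[p] == "(") {
      open <- c(open, p - 1L)
    } else if (chars[p] == ")") {
      if (length(open) == 0) stop("unbalanced dot-bracket", call. = FALSE)
      pairs <- rbind(pairs, c(open[length(open)], p - 1L))
      open <- open[-length(open)]
    }
  }
  if (length(open) > 0) stop("unbalanced dot-bracket", call. = FALSE)
  rna_structure(pairs, lengths)
}

nick_position <- function(lengths) {
  if (length(lengths) == 2) lengths[1] else -1L
}

nick_inside <- function(i, j, nick) nick > i & nick <= j

# Parent/child topology of a pair list. Returns, for each pair row, the row
# index of its innermost enclosing pair (NA for exterior pairs).
pair_parents <- function(pairs) {
  n <- nrow(pairs)
  parents <- rep(NA_integer_, n)
  if (n < 2) return(parents)
  for (p in seq_len(n)) {
    enc <- which(pairs[, 1] < pairs[p, 1] & pairs[, 2] > pairs[p, 2])
    if (length(enc) > 0) {
      parents[p] <- enc[which.min(pairs[enc, 2] - pairs[enc, 1])]
    }
  }
  parents
}

#' Validate a secondary structure for given strands
#'
#' @param strands Character vector of 1 or 2 RNA sequences.
#' @param structure An `rna_structure` (or dot-bracket string).
#' @param model An `energy_model` (for the minimum hairpin size).
#' @return Invisibly `TRUE`; errors describe the violated rule.
#' @export
validate_structure <- function(strands, structure, model = energy_model()) {
  if (is.character(structure)) structure <- db_to_structure(structure)
  stopifnot(inherits(structure, "rna_structure"))
  strands <- vapply(strands, as_rna, character(1), warn_lowercase = FALSE,
                    USE.NAMES = FALSE)
  lengths <- nchar(strands)
  if (!identical(as.integer(lengths), structure$lengths)) {
    stop("structure strand lengths do not match the strands", call. = FALSE)
  }
  n <- sum(lengths)
  nick <- nick_position(lengths)
  pairs <- structure$pairs
  if (nrow(pairs) == 0) {
    if (length(strands) == 2) stop("two-strand structure must be connected", call. = FALSE)
    return(invisible(TRUE))
  }
  idx <- c(pairs)
  if (any(idx < 0 | idx >= n)) stop("pair index out of range", call. = FALSE)
  if (anyDuplicated(idx)) stop("position in more than one pair", call. = FALSE)
  chars <- seq_chars(paste(strands, collapse = ""))
  pt <- pair_type(chars[pairs[, 1] + 1], chars[pairs[, 2] + 1])
  if (anyNA(pt)) stop("non-canonical base pair (only A-U, G-C, G-U allowed)", call. = FALSE)
  # non-crossing
  for (p in seq_len(nrow(pairs))) {
    cross <- pairs[, 1] < pairs[p, 1] & pairs[, 2] > pairs[p, 1] & pairs[, 2] < pairs[p, 2]
    if (any(cross)) stop("pseudoknotted (crossing) pairs", call. = FALSE)
  }
  # hairpin minimum
  parents <- pair_parents(pairs)
  for (p in seq_len(nrow(pairs))) {
    kids <- which(!is.na(parents) & parents == p)
    if (length(kids) == 0 && !nick_inside(pairs[p, 1], pairs[p, 2], nick) &&
        pairs[p, 2] - pairs[p, 1] - 1 < model$min_hairpin) {
      stop("hairpin loop smaller than 3 unpaired residues", call. = FALSE)
    }
  }
  if (length(strands) == 2 && !any(pairs[, 1] < nick & pairs[, 2] >= nick)) {
    stop("two-strand structure must be connected (no inter-strand pair)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Free energy of a secondary structure
#'
#' Reference (non-DP) evaluator: decomposes the structure into loops, sums
#' nearest-neighbor stack energies for adjacent pairs and size-dependent
#' hairpin/bulge/internal loop penalties, scores multibranch and exterior
#' loops (and any loop containing the strand nick) as zero, and adds the
#' duplex initiation penalty once per additional strand. The unpaired open
#' chain scores 0.
#'
#' @inheritParams validate_structure
#' @param check Validate the structure first.
#' @return Free energy in kcal/mol.
#' @examples
#' structure_energy("GGGGAAAACCCC", "((((....))))")
#' @export
structure_energy <- function(strands, structure, model = energy_model(), check = TRUE) {
  if (is.character(structure)) structure <- db_to_structure(structure)
  strands <- vapply(strands, as_rna, character(1), warn_lowercase = FALSE,
                    USE.NAMES = FALSE)
  if (check) validate_structure(strands, structure, model)
  pairs <- structure$pairs
  lengths <- nchar(strands)
  e <- (length(strands) - 1) * model$duplex_init_dG
  if (nrow(pairs) == 0) return(e)
  nick <- nick_position(lengths)
  chars <- seq_chars(paste(strands, collapse = ""))
  pen <- model_penalties(model, sum(lengths))
  parents <- pair_parents(pairs)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    kids <- which(!is.na(parents) & parents == p)
    e <- e + closing_loop_energy(
      i, j, pairs[kids, , drop = FALSE], chars, nick, model, pen
    )
  }
  e
}

# Energy of the loop closed by pair (i, j) given its direct inner branches.
closing_loop_energy <- function(i, j, kids, chars, nick, model, pen) {
  nb <- nrow(kids)
  if (nb >= 2) return(0) # multibranch loops carry no penalty in this model
  if (nb == 0) {
    if (nick_inside(i, j, nick)) return(0)
    return(pen$hairpin[j - i - 1])
  }
  k <- kids[1, 1]; l <- kids[1, 2]
  if (nick_inside(i, k, nick) || nick_inside(l, j, nick)) return(0)
  s1 <- k - i - 1; s2 <- j - l - 1
  if (s1 == 0 && s2 == 0) {
    p1 <- pair_type(chars[i + 1], chars[j + 1])
    p2 <- pair_type(chars[k + 1], chars[l + 1])
    return(model$stack_dG[p1, p2])
  }
  if (s1 == 0 || s2 == 0) return(pen$bulge[s1 + s2])
  pen$internal[s1 + s2]
}
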