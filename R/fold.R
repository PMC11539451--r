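# Folding, partition functions and the exhaustive enumeration oracle.

# Shared driver for the C++ dynamic program. strands: character vector of
# 1 or 2 RNA sequences; forbid: optional N x N logical matrix of forbidden
# (0-based) pairs.
run_dp <- function(strands, model, forbid = NULL) {
  strands <- vapply(strands, as_rna, character(1), warn_lowercase = FALSE,
                    USE.NAMES = FALSE)
  stopifnot(length(strands) %in% 1:2)
  concat <- paste(strands, collapse = "")
  n <- nchar(concat)
  pen <- model_penalties(model, n)
  thermo_dp(
    seq = encode_seq(concat),
    nick = nick_position(nchar(strands)),
    stack = model$stack_dG,
    hairpin = pen$hairpin, bulge = pen$bulge, internal = pen$internal,
    RT = model$RT,
    forbid = forbid,
    traceback = TRUE
  )
}

#' Minimum free energy structure
#'
#' Folds one strand (or an ordered two-strand complex) to its minimum free
#' energy secondary structure by dynamic programming. The open chain is the
#' reference state at 0 kcal/mol, so the reported energy is always <= 0 for
#' a single strand.
#'
#' @param strands Character vector of 1 or 2 RNA sequences (5'->3').
#' @param model An `energy_model`.
#' @param forbid Optional `N x N` logical matrix (0-based concatenated
#'   coordinates) marking forbidden pairs; used for conditional folding.
#' @return A list with `structure` (an [rna_structure]) and `dG` (kcal/mol;
#'   for dimers the duplex initiation penalty is included when any pair is
#'   formed).
#' @examples
#' fold_mfe("GGGGAAAACCCC")$structure
#' @export
fold_mfe <- function(strands, model = energy_model(), forbid = NULL) {
  res <- run_dp(strands, model, forbid)
  strands <- vapply(strands, as_rna, character(1), warn_lowercase = FALSE,
                    USE.NAMES = FALSE)
  if (length(strands) == 2) {
    # connected complex: best structure with at least one inter-strand pair
    st <- rna_structure(res$pairs_conn, nchar(strands))
    return(list(structure = st, dG = res$mfe_conn + model$duplex_init_dG))
  }
  list(structure = rna_structure(res$pairs, nchar(strands)), dG = res$mfe)
}

#' Is a sequence free of secondary structure?
#'
#' `TRUE` when the minimum free energy structure of the sequence is the open
#' chain (MFE = 0), the design requirement for toehold domains and trigger
#' RNAs. Diagnostics report the offending MFE structure otherwise.
#'
#' @param seq RNA sequence.
#' @param model An `energy_model`.
#' @return Logical scalar with a `diagnostics` attribute (empty tibble when
#'   unstructured).
#' @examples
#' is_unstructured("AAAAAAAAAA")
#' @export
is_unstructured <- function(seq, model = energy_model()) {
  f <- fold_mfe(seq, model)
  ok <- f$dG >= -1e-9
  diag <- if (ok) {
    tibble::tibble(dot_bracket = character(0), dG = numeric(0))
  } else {
    tibble::tibble(dot_bracket = f$structure$dot_bracket, dG = f$dG)
  }
  structure(ok, diagnostics = diag)
}

#' Partition function of a strand or two-strand complex
#'
#' `Q = sum over valid structures of exp(-dG / RT)`, computed by dynamic
#' programming. For dimers only connected structures (at least one
#' inter-strand pair) contribute and the duplex initiation penalty is
#' included. The ensemble free energy is `-RT log Q`.
#'
#' @inheritParams fold_mfe
#' @return List with `Q`, `logQ` and `dG` (kcal/mol).
#' @examples
#' partition_function("AAAA")$Q # 1: only the open chain
#' @export
partition_function <- function(strands, model = energy_model(), forbid = NULL) {
  strands <- vapply(strands, as_rna, character(1), warn_lowercase = FALSE,
                    USE.NAMES = FALSE)
  if (length(strands) == 1) {
    res <- run_dp(strands, model, forbid)
    return(list(Q = exp(res$logQ), logQ = res$logQ, dG = -model$RT * res$logQ))
  }
  res <- run_dp(strands, model, forbid)
  if (!is.finite(res$logQ_conn)) {
    # no connected structure exists
    return(list(Q = 0, logQ = -Inf, dG = Inf))
  }
  log_qconn <- res$logQ_conn - model$duplex_init_dG / model$RT
  list(Q = exp(log_qconn), logQ = log_qconn, dG = -model$RT * log_qconn)
}

#' Ensemble free energy of a heterodimer
#'
#' Ensemble (partition-function) free energy of the `a . b` complex over all
#' connected two-strand structures, duplex initiation included. Symmetric in
#' its arguments.
#'
#' @param a,b RNA sequences.
#' @param model An `energy_model`.
#' @return Free energy in kcal/mol (`Inf` when the strands cannot pair).
#' @export
duplex_dG <- function(a, b, model = energy_model()) {
  partition_function(c(a, b), model)$dG
}

#' Exhaustively enumerate all secondary structures
#'
#' Test oracle: every valid structure of a strand or ordered two-strand
#' complex, each exactly once, with its free energy. Guarded to a total
#' length of 20 because the structure count grows exponentially.
#'
#' @inheritParams fold_mfe
#' @param max_total_len Guard on the total sequence length.
#' @return Tibble with columns `dot_bracket`, `n_pairs`, `dG` (duplex
#'   initiation included for dimers; only connected dimer structures are
#'   listed).
#' @examples
#' enumerate_structures("GGGAAACCC")
#' @export
enumerate_structures <- function(strands, model = energy_model(),
                                 max_total_len = 20) {
  strands <- vapply(strands, as_rna, character(1), warn_lowercase = FALSE,
                    USE.NAMES = FALSE)
  stopifnot(length(strands) %in% 1:2)
  concat <- paste(strands, collapse = "")
  n <- nchar(concat)
  if (n > max_total_len) {
    stop("total length ", n, " exceeds the enumeration guard (", max_total_len, ")",
      call. = FALSE
    )
  }
  chars <- seq_chars(concat)
  lengths <- nchar(strands)
  nick <- nick_position(lengths)
  pen <- model_penalties(model, n)
  memo <- new.env(parent = emptyenv())

  can_pair <- function(i, j) {
    !is.na(pair_type(chars[i + 1], chars[j + 1])) &&
      (j - i - 1 >= model$min_hairpin || nick_inside(i, j, nick))
  }
  # Each structure: list(pairs, tops (2-col matrices), E)
  empty <- list(list(pairs = matrix(integer(0), ncol = 2),
                     tops = matrix(integer(0), ncol = 2), E = 0))
  enum_W <- function(i, j) {
    if (i > j) return(empty)
    key <- paste0("W", i, ":", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- enum_W(i, j - 1) # j unpaired
    for (k in i:j) {
      if (k == j) break
      vs <- enum_V(k, j)
      if (length(vs) == 0) next
      ls <- enum_W(i, k - 1)
      for (l in ls) {
        for (v in vs) {
          out[[length(out) + 1]] <- list(
            pairs = rbind(l$pairs, v$pairs),
            tops = rbind(l$tops, v$tops[1, , drop = FALSE]),
            E = l$E + v$E
          )
        }
      }
    }
    memo[[key]] <- out
    out
  }
  enum_V <- function(i, j) {
    key <- paste0("V", i, ":", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- list()
    if (can_pair(i, j)) {
      for (st in enum_W(i + 1, j - 1)) {
        ce <- closing_loop_energy(i, j, st$tops, chars, nick, model, pen)
        if (!is.finite(ce)) next
        out[[length(out) + 1]] <- list(
          pairs = rbind(st$pairs, c(i, j)),
          tops = matrix(c(i, j), ncol = 2),
          E = st$E + ce
        )
      }
    }
    memo[[key]] <- out
    out
  }

  all <- enum_W(0L, n - 1L)
  if (length(lengths) == 2) {
    keep <- vapply(all, function(st) {
      nrow(st$pairs) > 0 && any(st$pairs[, 1] < nick & st$pairs[, 2] >= nick)
    }, logical(1))
    all <- all[keep]
  }
  init <- (length(lengths) - 1) * model$duplex_init_dG
  tibble::tibble(
    dot_bracket = vapply(all, function(st) pairs_to_db(st$pairs, lengths), character(1)),
    n_pairs = vapply(all, function(st) nrow(st$pairs), integer(1)),
    dG = vapply(all, function(st) st$E + init, numeric(1))
  )
}

#' Count secondary structures by recursion
#'
#' Independent structure counter (no energies, no enumeration): counts valid
#' structures over the concatenated strands via interval recursion. Used to
#' cross-check [enumerate_structures()].
#'
#' @inheritParams enumerate_structures
#' @return Number of valid structures (including the open chain; for dimers
#'   disconnected structures are included, so compare against enumeration of
#'   the monomers plus connected dimers).
#' @export
count_structures <- function(strands, model = energy_model(), max_total_len = 25) {
  strands <- vapply(strands, as_rna, character(1), warn_lowercase = FALSE,
                    USE.NAMES = FALSE)
  concat <- paste(strands, collapse = "")
  n <- nchar(concat)
  if (n > max_total_len) stop("sequence too long for counting guard", call. = FALSE)
  chars <- seq_chars(concat)
  nick <- nick_position(nchar(strands))
  memo <- array(NA_real_, dim = c(n + 1, n + 1))
  can_pair <- function(i, j) {
    !is.na(pair_type(chars[i + 1], chars[j + 1])) &&
      (j - i - 1 >= model$min_hairpin || nick_inside(i, j, nick))
  }
  cw <- function(i, j) {
    if (i > j) return(1)
    if (!is.na(memo[i + 1, j + 1])) return(memo[i + 1, j + 1])
    total <- cw(i, j - 1)
    for (k in i:j) {
      if (k == j) break
      if (can_pair(k, j)) total <- total + cw(i, k - 1) * cw(k + 1, j - 1)
    }
    memo[i + 1, j + 1] <<- total
    total
  }
  cw(0L, n - 1L)
}
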