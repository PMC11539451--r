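GAS_CONSTANT <- 0.0019872 # kcal / (mol K)

PAIR_TYPES <- c("AU", "UA", "CG", "GC", "GU", "UG")

rev_pair <- function(p) {
  c(AU = "UA", UA = "AU", CG = "GC", GC = "CG", GU = "UG", UG = "GU")[p]
}

#' Nearest-neighbor RNA energy model
#'
#' Builds the free-energy model used by all folding, partition-function and
#' equilibrium computations: Watson-Crick and G-U wobble stack energies,
#' size-dependent hairpin/bulge/internal loop penalties with logarithmic
#' extrapolation beyond the tabulated sizes, and a bimolecular duplex
#' initiation penalty. Parameters are a bundled Turner-style 37 degree C
#' table; free energies are held fixed when the temperature is changed
#' (no enthalpy/entropy separation), so temperature only rescales `RT`.
#'
#' Simplifications (documented): no coaxial stacking, no dangles, no
#' terminal-pair penalties, size-only internal/bulge penalties, no
#' pseudoknots, minimum hairpin loop of 3, zero multiloop penalty, and no
#' homodimer rotational-symmetry correction.
#'
#' @param temperature Temperature in kelvin (default 310.15, i.e. 37 C).
#' @param duplex_init Bimolecular association penalty in kcal/mol.
#' @return An object of class `energy_model`.
#' @examples
#' m <- energy_model()
#' m$RT
#' @export
energy_model <- function(temperature = 310.15, duplex_init = 4.09) {
  stopifnot(temperature > 0)
  stacks <- utils::read.csv(
    system.file("extdata", "rna_stacks_dG37.csv", package = "swtdesign"),
    comment.char = "#"
  )
  loops <- utils::read.csv(
    system.file("extdata", "rna_loops_dG37.csv", package = "swtdesign"),
    comment.char = "#"
  )
  stack_dG <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_TYPES, PAIR_TYPES))
  for (r in seq_len(nrow(stacks))) {
    p1 <- stacks$pair1[r]; p2 <- stacks$pair2[r]; e <- stacks$dG[r]
    stack_dG[p1, p2] <- e
    stack_dG[rev_pair(p2), rev_pair(p1)] <- e
  }
  if (anyNA(stack_dG)) stop("incomplete stack table", call. = FALSE)
  loop_tab <- function(kind) {
    sub <- loops[loops$kind == kind, ]
    stats::setNames(sub$dG, sub$size)
  }
  structure(
    list(
      stack_dG = stack_dG,
      hairpin_dG = loop_tab("hairpin"),
      bulge_dG = loop_tab("bulge"),
      internal_dG = loop_tab("internal"),
      duplex_init_dG = duplex_init,
      temperature = temperature,
      RT = GAS_CONSTANT * temperature,
      min_hairpin = 3L
    ),
    class = "energy_model"
  )
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf(
    "<energy_model> T = %.2f K (RT = %.4f kcal/mol), duplex init %.2f kcal/mol\n",
    x$temperature, x$RT, x$duplex_init_dG
  ))
  invisible(x)
}

# Size-indexed loop penalty vector up to length n, with log extrapolation
# dG(k) = dG(kmax) + 1.75 RT log(k / kmax) beyond the table.
loop_penalties <- function(tab, n, RT) {
  sizes <- as.integer(names(tab))
  kmax <- max(sizes)
  out <- rep(Inf, max(n, 1L))
  for (k in seq_len(max(n, 1L))) {
    out[k] <- if (k %in% sizes) {
      tab[[as.character(k)]]
    } else if (k > kmax) {
      tab[[as.character(kmax)]] + 1.75 * RT * log(k / kmax)
    } else {
      Inf # below the smallest tabulated size: disallowed
    }
  }
  out
}

# Penalty vectors sized for a total sequence length n.
model_penalties <- function(model, n) {
  list(
    hairpin = loop_penalties(model$hairpin_dG, n, model$RT),
    bulge = loop_penalties(model$bulge_dG, n, model$RT),
    internal = loop_penalties(model$internal_dG, n, model$RT)
  )
}

BASES <- c("A", "C", "G", "U")

# Encode a sequence as integers 0..3 (A,C,G,U) for the C++ engine.
encode_seq <- function(seq) {
  match(seq_chars(seq), BASES) - 1L
}

# Pair type index (1..6) or NA if not pairable; i/j are bases as letters.
pair_type <- function(a, b) {
  match(paste0(a, b), PAIR_TYPES)
}
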