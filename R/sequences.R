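#' Coerce a character vector to canonical RNA
#'
#' Sequences are handled internally as uppercase RNA (`A`, `C`, `G`, `U`),
#' written 5'->3'. DNA input (containing `T`) is transcribed on read; mixed
#' `U`/`T` input is rejected because its intent is ambiguous.
#'
#' @param x Character vector of sequences (RNA or DNA).
#' @param warn_lowercase Warn when lowercase letters are uppercased.
#' @return Character vector of validated RNA sequences.
#' @examples
#' as_rna("acgt")
#' @export
as_rna <- function(x, warn_lowercase = TRUE) {
  stopifnot(is.character(x))
  if (warn_lowercase && any(grepl("[a-z]", x))) {
    warning("lowercase residues uppercased", call. = FALSE)
  }
  x <- toupper(x)
  mixed <- grepl("U", x, fixed = TRUE) & grepl("T", x, fixed = TRUE)
  if (any(mixed)) {
    stop("sequence mixes U and T; supply pure RNA or pure DNA", call. = FALSE)
  }
  x <- gsub("T", "U", x, fixed = TRUE)
  validate_rna(x)
  x
}

#' Validate RNA sequences
#'
#' Checks that every residue is one of `A`, `C`, `G`, `U` and that sequences
#' are non-empty. The error names the first offending position.
#'
#' @param x Character vector of RNA sequences.
#' @return Invisibly, `x`.
#' @export
validate_rna <- function(x) {
  stopifnot(is.character(x))
  if (any(!nzchar(x)) || anyNA(x)) stop("empty sequence", call. = FALSE)
  bad <- regexpr("[^ACGU]", x)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf(
      "invalid residue '%s' at position %d of sequence %d",
      substr(x[i], bad[i], bad[i]), bad[i], i
    ), call. = FALSE)
  }
  invisible(x)
}

#' Reverse complement of an RNA sequence
#'
#' Watson-Crick complement (A<->U, C<->G), reversed. Applying it twice
#' returns the input.
#'
#' @param seq RNA sequence (character scalar or vector).
#' @return Reverse-complemented sequence(s).
#' @examples
#' revcomp("AAGG") # "CCUU"
#' @export
revcomp <- function(seq) {
  validate_rna(seq)
  vapply(seq, function(s) {
    chartr("ACGU", "UGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' GC fraction of a sequence
#'
#' @param seq RNA sequence (character scalar or vector).
#' @return Numeric in `[0, 1]`: (#G + #C) / length.
#' @examples
#' gc_fraction("GCAU") # 0.5
#' @export
gc_fraction <- function(seq) {
  validate_rna(seq)
  gc <- nchar(gsub("[^GC]", "", seq))
  gc / nchar(seq)
}

seq_chars <- function(seq) strsplit(seq, "")[[1]]

#' Built-in stem-loop presets
#'
#' Named presets for the terminator stem-loop. The reference T500 stem-loop
#' sequence is published only in supplementary material not bundled here, so
#' the shipped presets are *synthetic* stand-ins that reproduce the stated
#' architecture: `t500_synthetic` is a 7-bp all-GC stem with a stable UUCG
#' tetraloop (the T500 architecture: a strong 7-bp, 100% GC stem and a small
#' loop); `expanded_synthetic` is a 10-bp stem with exactly one A-U pair
#' (90% GC), the expanded design regime.
#'
#' @param name Preset name; `NULL` lists all presets.
#' @return A tibble with columns `preset`, `stem5`, `loop`.
#' @export
swt_presets <- function(name = NULL) {
  presets <- tibble::tribble(
    ~preset,              ~stem5,        ~loop,
    "t500_synthetic",     "GGCGGCC",     "UUCG",
    "expanded_synthetic", "GGCAGCGGCC",  "UUCG"
  )
  if (is.null(name)) return(presets)
  hit <- presets[presets$preset == name, ]
  if (nrow(hit) == 0) {
    stop("unknown preset: ", name, call. = FALSE)
  }
  hit
}

#' Assemble a switchable transcription terminator (SWT)
#'
#' An SWT transcript is `toehold || stem5 || loop || stem3 || polyU` in
#' 5'->3' order, where `stem3` is derived automatically as the reverse
#' complement of `stem5` and the poly-U tract terminates transcription.
#'
#' @param name Construct identifier.
#' @param toehold Single-stranded toehold sequence (default length 40).
#' @param stem5 5' arm of the terminator hairpin stem.
#' @param loop Hairpin loop sequence (>= 3 nt for a foldable hairpin).
#' @param polyU_len Length of the poly-U tract (>= 6).
#' @param toehold_length Expected toehold length; mismatches error unless
#'   `strict = FALSE`.
#' @param strict Enforce the configured toehold length.
#' @return An object of class `swt_design`.
#' @examples
#' s <- swt("demo", toehold = "AAGG", stem5 = "CCGG", loop = "GAAA",
#'          polyU_len = 6, strict = FALSE)
#' swt_transcript(s)
#' @export
swt <- function(name, toehold, stem5, loop, polyU_len = 8,
                toehold_length = 40, strict = TRUE) {
  stopifnot(is.character(name), length(name) == 1)
  toehold <- as_rna(toehold, warn_lowercase = FALSE)
  stem5 <- as_rna(stem5, warn_lowercase = FALSE)
  loop <- as_rna(loop, warn_lowercase = FALSE)
  if (polyU_len < 6) {
    stop("polyU_len must be >= 6 for an effective poly-U tract", call. = FALSE)
  }
  if (strict && nchar(toehold) != toehold_length) {
    stop(sprintf(
      "toehold length %d does not match configured length %d (use strict = FALSE to override)",
      nchar(toehold), toehold_length
    ), call. = FALSE)
  }
  structure(
    list(
      name = name, toehold = toehold, stem5 = stem5, loop = loop,
      stem3 = revcomp(stem5), polyU = strrep("U", polyU_len)
    ),
    class = "swt_design"
  )
}

#' @export
print.swt_design <- function(x, ...) {
  cat("<swt_design>", x$name, "\n")
  d <- swt_domains(x)
  cat(sprintf(
    "  %d nt: toehold %d | stem %d bp | loop %d | polyU %d\n",
    nchar(swt_transcript(x)), nchar(x$toehold), nchar(x$stem5),
    nchar(x$loop), nchar(x$polyU)
  ))
  cat("  ", swt_transcript(x), "\n", sep = "")
  invisible(x)
}

#' Full SWT transcript sequence
#'
#' @param x An `swt_design`.
#' @return Character scalar, the 5'->3' transcript.
#' @export
swt_transcript <- function(x) {
  stopifnot(inherits(x, "swt_design"))
  paste0(x$toehold, x$stem5, x$loop, x$stem3, x$polyU)
}

#' Domain coordinates of an SWT
#'
#' Coordinates are 0-based, half-open (`start:end` covers residues
#' `start .. end-1` of the transcript).
#'
#' @param x An `swt_design`.
#' @return Tibble with columns `domain`, `start`, `end`, `seq`.
#' @export
swt_domains <- function(x) {
  stopifnot(inherits(x, "swt_design"))
  seqs <- c(x$toehold, x$stem5, x$loop, x$stem3, x$polyU)
  len <- nchar(seqs)
  end <- cumsum(len)
  tibble::tibble(
    domain = c("toehold", "stem5", "loop", "stem3", "polyU"),
    start = end - len, end = end, seq = seqs
  )
}

trigger_modes <- c("toehold_only", "stem_only", "toehold_stem", "toehold_stem_loop")

#' Derive a trigger RNA from an SWT
#'
#' The trigger is the reverse complement of the SWT domains selected by
#' `mode`. The default, `"toehold_stem"`, spans both the toehold and the
#' stem 5' arm; triggers carrying only one of the two domains are
#' insufficient to disrupt the terminator and are provided for screening.
#'
#' @param swt An `swt_design`.
#' @param mode One of `"toehold_only"`, `"stem_only"`, `"toehold_stem"`,
#'   `"toehold_stem_loop"`.
#' @param name Trigger identifier; default derives from the SWT name.
#' @return An object of class `trigger_design`.
#' @examples
#' s <- swt("demo", "AAGG", "CCGG", "GAAA", polyU_len = 6, strict = FALSE)
#' trigger(s, "toehold_stem")$sequence # "CCGGCCUU"
#' @export
trigger <- function(swt, mode = "toehold_stem", name = NULL) {
  stopifnot(inherits(swt, "swt_design"))
  mode <- match.arg(mode, trigger_modes)
  target <- switch(mode,
    toehold_only = swt$toehold,
    stem_only = swt$stem5,
    toehold_stem = paste0(swt$toehold, swt$stem5),
    toehold_stem_loop = paste0(swt$toehold, swt$stem5, swt$loop)
  )
  structure(
    list(
      name = name %||% paste0("T_", swt$name),
      mode = mode,
      sequence = revcomp(target),
      cognate = swt$name
    ),
    class = "trigger_design"
  )
}

#' @export
print.trigger_design <- function(x, ...) {
  cat("<trigger_design>", x$name, sprintf("(mode %s, cognate %s)\n", x$mode, x$cognate))
  cat("  ", x$sequence, "\n", sep = "")
  invisible(x)
}

#' Size of the terminator stem design space
#'
#' Counts distinct stem duplexes of a given length in which every base pair
#' is Watson-Crick, exactly `n_nonGC` pairs are A-U or U-A, and the rest are
#' G-C or C-G: `choose(length, n_nonGC) * 2^length`. Relaxing the original
#' 7-bp all-GC stem to 10 bp with exactly one non-GC pair expands the space
#' 80-fold.
#'
#' @param length Stem length in base pairs.
#' @param n_nonGC Exact number of A-U/U-A pairs.
#' @return Number of distinct duplexes (numeric).
#' @examples
#' stem_space_size(10, 1) / stem_space_size(7, 0) # 80
#' @export
stem_space_size <- function(length, n_nonGC) {
  stopifnot(length >= 1, n_nonGC >= 0, n_nonGC <= length)
  choose(length, n_nonGC) * 2^length
}

#' Enumerate seeded stem-arm variants
#'
#' Generates terminator stem 5' arms for each combination of `lengths` and
#' `gc_fracs`. The GC target is operationalized per base pair: a fraction
#' `g` at length `L` means exactly `round(g * L)` G/C pairs, which keeps the
#' realized GC fraction within `1/L` of the target. Sampling is driven by
#' the current R RNG, so `set.seed()` makes the output deterministic.
#'
#' @param lengths Integer vector of stem lengths (>= 4 bp).
#' @param gc_fracs Numeric vector of GC targets in `[0, 1]`.
#' @param n_per Number of variants per (length, GC) combination.
#' @return Tibble with columns `name`, `length`, `gc_target`, `gc_fraction`,
#'   `sequence` (the 5' arm; the 3' arm is its reverse complement).
#' @export
stem_variants <- function(lengths = c(7, 10, 13), gc_fracs = c(0.7, 0.8, 0.9, 1.0),
                          n_per = 3) {
  stopifnot(all(lengths >= 4), all(gc_fracs >= 0 & gc_fracs <= 1), n_per >= 1)
  grid <- tidyr::expand_grid(length = as.integer(lengths), gc_target = gc_fracs)
  purrr::pmap_dfr(grid, function(length, gc_target) {
    n_gc <- round(gc_target * length)
    if (n_gc < 0 || n_gc > length) {
      stop("infeasible GC/length combination", call. = FALSE)
    }
    arms <- vapply(seq_len(n_per), function(i) sample_stem_arm(length, length - n_gc),
      character(1)
    )
    tibble::tibble(
      name = sprintf("stem_L%d_gc%02d_%d", length, round(100 * gc_target), seq_len(n_per)),
      length = length, gc_target = gc_target,
      gc_fraction = gc_fraction(arms), sequence = arms
    )
  })
}

# Draw one stem 5' arm with exactly n_nonGC A/U positions (uses the R RNG).
sample_stem_arm <- function(length, n_nonGC) {
  stopifnot(n_nonGC >= 0, n_nonGC <= length)
  pos_au <- sort(sample.int(length, n_nonGC))
  res <- sample(c("G", "C"), length, replace = TRUE)
  if (n_nonGC > 0) res[pos_au] <- sample(c("A", "U"), n_nonGC, replace = TRUE)
  paste(res, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
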