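# Automated design of orthogonal SWT/trigger libraries: seeded candidate
# generation, constraint filtering, equilibrium crosstalk screening, and
# greedy library assembly.

#' Design constraints for SWT library generation
#'
#' Defaults encode the screening conditions used throughout the pipeline:
#' 40-nt random toeholds with 50-60% GC and no secondary structure, a 10-bp
#' terminator stem with exactly one non-GC pair (the expanded stem design
#' space), triggers spanning toehold + stem and required to be linear,
#' all-species screening at 10 nM, and acceptance thresholds of >= 0.90
#' predicted activation on-target and <= 0.05 off-target.
#'
#' @param toehold_length Toehold length in nt.
#' @param toehold_gc_window Closed GC-fraction window for the toehold.
#' @param stem_length Terminator stem length in bp.
#' @param stem_nonGC_pairs Exact number of A-U/U-A pairs in the stem.
#' @param loop Hairpin loop sequence.
#' @param polyU_len Poly-U tract length.
#' @param require_unstructured_toehold Reject toeholds with any predicted
#'   secondary structure.
#' @param trigger_mode Trigger derivation mode (see [trigger()]).
#' @param trigger_linear_required Reject candidates whose trigger folds.
#' @param concentration Screening concentration (molar) per species.
#' @param crosstalk_threshold Maximum tolerated off-target activation.
#' @param cognate_min_activation Minimum on-target activation.
#' @param max_candidates_per_slot Sampling budget per library slot.
#' @param trigger_duplex_warn_dG Warn when a trigger-trigger ensemble free
#'   energy (kcal/mol) is below this bound.
#' @return An object of class `design_constraints`.
#' @export
design_constraints <- function(toehold_length = 40,
                               toehold_gc_window = c(0.50, 0.60),
                               stem_length = 10,
                               stem_nonGC_pairs = 1,
                               loop = "UUCG",
                               polyU_len = 8,
                               require_unstructured_toehold = TRUE,
                               trigger_mode = "toehold_stem",
                               trigger_linear_required = TRUE,
                               concentration = 1e-8,
                               crosstalk_threshold = 0.05,
                               cognate_min_activation = 0.90,
                               max_candidates_per_slot = 10000,
                               trigger_duplex_warn_dG = -9) {
  stopifnot(
    length(toehold_gc_window) == 2,
    all(toehold_gc_window >= 0 & toehold_gc_window <= 1),
    toehold_gc_window[1] <= toehold_gc_window[2],
    stem_nonGC_pairs >= 0, stem_nonGC_pairs <= stem_length,
    concentration > 0,
    crosstalk_threshold < cognate_min_activation
  )
  structure(
    list(
      toehold_length = as.integer(toehold_length),
      toehold_gc_window = toehold_gc_window,
      stem_length = as.integer(stem_length),
      stem_nonGC_pairs = as.integer(stem_nonGC_pairs),
      loop = as_rna(loop, warn_lowercase = FALSE),
      polyU_len = as.integer(polyU_len),
      require_unstructured_toehold = isTRUE(require_unstructured_toehold),
      trigger_mode = match.arg(trigger_mode, trigger_modes),
      trigger_linear_required = isTRUE(trigger_linear_required),
      concentration = concentration,
      crosstalk_threshold = crosstalk_threshold,
      cognate_min_activation = cognate_min_activation,
      max_candidates_per_slot = as.integer(max_candidates_per_slot),
      trigger_duplex_warn_dG = trigger_duplex_warn_dG
    ),
    class = "design_constraints"
  )
}

#' @export
print.design_constraints <- function(x, ...) {
  cat("<design_constraints>\n")
  cat(sprintf(
    "  toehold %d nt, GC [%.2f, %.2f]%s\n", x$toehold_length,
    x$toehold_gc_window[1], x$toehold_gc_window[2],
    if (x$require_unstructured_toehold) ", unstructured" else ""
  ))
  cat(sprintf(
    "  stem %d bp with %d non-GC pair(s); trigger mode %s\n",
    x$stem_length, x$stem_nonGC_pairs, x$trigger_mode
  ))
  cat(sprintf(
    "  screen at %.3g M; on-target >= %.2f, off-target <= %.2f\n",
    x$concentration, x$cognate_min_activation, x$crosstalk_threshold
  ))
  invisible(x)
}

#' Sample a toehold sequence under the design constraints
#'
#' Draws random toeholds from the configured length and GC window and,
#' when required, rejection-samples until the toehold has no predicted
#' secondary structure. Driven by the R RNG (`set.seed()` for
#' reproducibility).
#'
#' @param constraints A `design_constraints`.
#' @param model An `energy_model`.
#' @param budget Maximum number of draws before giving up.
#' @return Toehold sequence with attribute `attempts`.
#' @export
sample_toehold <- function(constraints = design_constraints(),
                           model = energy_model(),
                           budget = constraints$max_candidates_per_slot) {
  n <- constraints$toehold_length
  win <- constraints$toehold_gc_window
  for (attempt in seq_len(budget)) {
    s <- paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
    g <- gc_fraction(s)
    if (g < win[1] || g > win[2]) next
    if (constraints$require_unstructured_toehold && !is_unstructured(s, model)) next
    return(structure(s, attempts = attempt))
  }
  stop(
    "toehold sampling budget exhausted; consider relaxing the GC window or ",
    "the unstructured-toehold requirement",
    call. = FALSE
  )
}

#' Pair an SWT with its cognate trigger
#'
#' @param swt An `swt_design`.
#' @param trigger A `trigger_design` cognate to `swt` (derived automatically
#'   when omitted).
#' @param mode Trigger mode used when deriving.
#' @return An object of class `candidate_pair`.
#' @export
candidate_pair <- function(swt, trigger = NULL, mode = "toehold_stem") {
  stopifnot(inherits(swt, "swt_design"))
  if (is.null(trigger)) trigger <- trigger(swt, mode)
  stopifnot(inherits(trigger, "trigger_design"))
  if (trigger$cognate != swt$name) {
    stop("trigger is not cognate to the SWT", call. = FALSE)
  }
  structure(list(swt = swt, trigger = trigger, diagnostics = NULL),
            class = "candidate_pair")
}

#' @export
print.candidate_pair <- function(x, ...) {
  cat("<candidate_pair>", x$swt$name, "/", x$trigger$name, "\n")
  if (!is.null(x$diagnostics)) print(x$diagnostics)
  invisible(x)
}

# Expected hairpin pairs of an SWT in 0-based transcript coordinates.
swt_stem_pairs <- function(swt) {
  d <- swt_domains(swt)
  s5 <- d[d$domain == "stem5", ]
  s3 <- d[d$domain == "stem3", ]
  L <- s5$end - s5$start
  cbind(s5$start + seq_len(L) - 1L, s3$end - seq_len(L))
}

# N x N logical mask forbidding all stem5 x stem3 pairs of an SWT placed at
# `offset` within a concatenation of total length `total_len`.
stem_forbid_mask <- function(swt, total_len, offset = 0L) {
  d <- swt_domains(swt)
  s5 <- d[d$domain == "stem5", ]
  s3 <- d[d$domain == "stem3", ]
  mask <- matrix(FALSE, total_len, total_len)
  i <- offset + seq.int(s5$start, s5$end - 1L)
  j <- offset + seq.int(s3$start, s3$end - 1L)
  mask[i + 1L, j + 1L] <- TRUE
  mask
}

#' Predicted activation of an SWT by a trigger
#'
#' Equilibrium surrogate for the ON state: the fraction of the SWT strand
#' that is both bound to the trigger and has its terminator stem displaced.
#' A two-species tube (each strand at the screening concentration, maximum
#' complex size 2) is solved; within the SWT-trigger complex ensemble, the
#' probability that no stem5:stem3 pair is formed is computed from a
#' conditional partition function with those pairs forbidden.
#' `state = "bound"` instead returns the plain bound fraction
#' (`[SWT.trigger] / total SWT`), which saturates for any long complementary
#' stretch and does not discriminate trigger modes.
#'
#' @param swt An `swt_design`.
#' @param trig A `trigger_design` (cognate or not).
#' @param constraints A `design_constraints` (supplies the concentration).
#' @param model An `energy_model`.
#' @param state `"switched"` (default) or `"bound"`.
#' @return Fraction in `[0, 1]`.
#' @export
predicted_activation <- function(swt, trig, constraints = design_constraints(),
                                 model = energy_model(),
                                 state = c("switched", "bound")) {
  state <- match.arg(state)
  stopifnot(inherits(swt, "swt_design"), inherits(trig, "trigger_design"))
  S <- swt_transcript(swt)
  Tr <- trig$sequence
  tb <- tube(c(S = S, T = Tr), concentrations = constraints$concentration)
  res <- equilibrium_concentrations(tb, model)
  fb <- bound_fraction(res, "S", "T")
  if (state == "bound") return(fb)
  nS <- nchar(S)
  mask <- stem_forbid_mask(swt, nS + nchar(Tr))
  dimer_tot <- run_dp(c(S, Tr), model)
  dimer_open <- run_dp(c(S, Tr), model, forbid = mask)
  p_open_dimer <- if (is.finite(dimer_open$logQ_conn) && is.finite(dimer_tot$logQ_conn)) {
    exp(dimer_open$logQ_conn - dimer_tot$logQ_conn)
  } else 0
  mono_tot <- run_dp(S, model)
  mono_open <- run_dp(S, model, forbid = mask[seq_len(nS), seq_len(nS), drop = FALSE])
  p_open_mono <- exp(mono_open$logQ - mono_tot$logQ)
  free_S <- attr(res, "free_fraction")[["S"]]
  act <- fb * p_open_dimer + free_S * p_open_mono
  min(max(act, 0), 1)
}

ideal_hairpin_energy <- function(swt, model) {
  structure_energy(
    swt_transcript(swt),
    rna_structure(swt_stem_pairs(swt), nchar(swt_transcript(swt))),
    model,
    check = FALSE
  )
}

# Structure-defect objective for a candidate: 0 iff the toehold and trigger
# are unstructured and no structure beats the bare terminator hairpin.
candidate_defect <- function(toehold, stem5, constraints, model) {
  cand <- swt("x", toehold, stem5, constraints$loop, constraints$polyU_len,
              toehold_length = constraints$toehold_length, strict = FALSE)
  trig <- trigger(cand, constraints$trigger_mode)
  f_th <- fold_mfe(toehold, model)
  f_tr <- fold_mfe(trig$sequence, model)
  f_sw <- fold_mfe(swt_transcript(cand), model)
  d <- -f_th$dG - f_tr$dG + (ideal_hairpin_energy(cand, model) - f_sw$dG)
  list(defect = d, swt = cand, trigger = trig,
       folds = list(toehold = f_th, trigger = f_tr, swt = f_sw))
}

# Map violating pair positions back onto mutable toehold / stem-arm indices.
violating_sites <- function(cand, folds, constraints) {
  L_th <- nchar(cand$toehold)
  L_st <- nchar(cand$stem5)
  th_sites <- integer(0)
  st_sites <- integer(0)
  take <- function(pos, origin) {
    # origin: "toehold" (toehold idx), "trigger" or "swt" (concat idx)
    for (p in pos) {
      if (origin == "toehold") {
        th_sites <<- c(th_sites, p)
      } else if (origin == "trigger") {
        if (p < L_st) st_sites <<- c(st_sites, L_st - 1L - p)
        else if (p < L_st + L_th) th_sites <<- c(th_sites, L_th - 1L - (p - L_st))
      } else {
        if (p < L_th) th_sites <<- c(th_sites, p)
        else if (p < L_th + L_st) st_sites <<- c(st_sites, p - L_th)
      }
    }
  }
  take(c(folds$toehold$structure$pairs), "toehold")
  take(c(folds$trigger$structure$pairs), "trigger")
  hp <- folds$swt$structure$pairs
  if (nrow(hp) > 0) {
    want <- swt_stem_pairs(cand)
    extra <- !apply(hp, 1, function(p) any(want[, 1] == p[1] & want[, 2] == p[2]))
    take(c(hp[extra, , drop = FALSE]), "swt")
  }
  list(toehold = unique(th_sites), stem = unique(st_sites))
}

# Seeded mutation-repair walk: drive the structure-defect objective to zero
# by point mutations at positions involved in unwanted pairs, keeping the
# toehold GC window and the stem composition (exact non-GC pair count)
# invariant. Returns NULL when no defect-free candidate is reached.
repair_candidate <- function(toehold, stem5, constraints, model,
                             max_steps = 400, patience = 60) {
  cur <- candidate_defect(toehold, stem5, constraints, model)
  steps <- 0L
  stalls <- 0L
  win <- constraints$toehold_gc_window
  while (cur$defect > 1e-9 && steps < max_steps && stalls < patience) {
    steps <- steps + 1L
    sites <- violating_sites(cur$swt, cur$folds, constraints)
    mutate_stem <- length(sites$stem) > 0 &&
      (length(sites$toehold) == 0 || stats::runif(1) < 0.25)
    new_th <- toehold
    new_st <- stem5
    if (mutate_stem) {
      pos <- sites$stem[sample.int(length(sites$stem), 1)] + 1L
      ch <- seq_chars(stem5)
      if (ch[pos] %in% c("A", "U")) {
        # move or flip the non-GC pair
        if (stats::runif(1) < 0.5) {
          ch[pos] <- setdiff(c("A", "U"), ch[pos])
        } else {
          gc_pos <- which(ch %in% c("G", "C"))
          swap <- gc_pos[sample.int(length(gc_pos), 1)]
          ch[swap] <- sample(c("A", "U"), 1)
          ch[pos] <- sample(c("G", "C"), 1)
        }
      } else {
        ch[pos] <- setdiff(c("G", "C"), ch[pos])
      }
      new_st <- paste(ch, collapse = "")
    } else {
      cand_sites <- if (length(sites$toehold) > 0) sites$toehold else
        seq_len(nchar(toehold)) - 1L
      pos <- cand_sites[sample.int(length(cand_sites), 1)] + 1L
      ch <- seq_chars(toehold)
      repl <- sample(setdiff(c("A", "C", "G", "U"), ch[pos]), 1)
      ch[pos] <- repl
      cand_th <- paste(ch, collapse = "")
      g <- gc_fraction(cand_th)
      if (g < win[1] || g > win[2]) next
      new_th <- cand_th
    }
    prop <- candidate_defect(new_th, new_st, constraints, model)
    if (prop$defect < cur$defect - 1e-9) {
      cur <- prop
      toehold <- new_th
      stem5 <- new_st
      stalls <- 0L
    } else {
      stalls <- stalls + 1L
    }
  }
  if (cur$defect > 1e-9) return(NULL)
  structure(list(toehold = toehold, stem5 = stem5, steps = steps), steps = steps)
}

#' Constraint diagnostics for a candidate SWT/trigger pair
#'
#' Evaluates, without short-circuiting: the toehold GC window; absence of
#' toehold secondary structure in isolation; that the SWT's own MFE
#' structure forms the full terminator hairpin with the toehold unpaired;
#' that the trigger is linear; and that the MFE structure of the SWT-trigger
#' complex hybridizes the complete target region (toehold + stem 5' arm for
#' the default trigger mode).
#'
#' @param pair A `candidate_pair`.
#' @param constraints A `design_constraints`.
#' @param model An `energy_model`.
#' @return Tibble with columns `check`, `value`, `pass`, `detail`.
#' @export
check_candidate <- function(pair, constraints = design_constraints(),
                            model = energy_model()) {
  stopifnot(inherits(pair, "candidate_pair"))
  swt <- pair$swt
  trig <- pair$trigger
  S <- swt_transcript(swt)
  rows <- list()
  add <- function(check, value, pass, detail = "") {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      check = check, value = value, pass = pass, detail = detail
    )
  }

  g <- gc_fraction(swt$toehold)
  win <- constraints$toehold_gc_window
  add("toehold_gc", g, g >= win[1] & g <= win[2],
      sprintf("window [%.2f, %.2f]", win[1], win[2]))

  th_fold <- fold_mfe(swt$toehold, model)
  add("toehold_unstructured", th_fold$dG, th_fold$dG >= -1e-9,
      th_fold$structure$dot_bracket)

  swt_fold <- fold_mfe(S, model)
  want <- swt_stem_pairs(swt)
  have <- swt_fold$structure$pairs
  stem_formed <- sum(apply(want, 1, function(p) {
    any(have[, 1] == p[1] & have[, 2] == p[2])
  })) / nrow(want)
  d <- swt_domains(swt)
  th_end <- d$end[d$domain == "toehold"]
  toehold_paired <- any(have < th_end)
  add("terminator_is_mfe", stem_formed,
      stem_formed == 1 && !toehold_paired,
      swt_fold$structure$dot_bracket)

  if (constraints$trigger_linear_required) {
    tr_fold <- fold_mfe(trig$sequence, model)
    add("trigger_linear", tr_fold$dG, tr_fold$dG >= -1e-9,
        tr_fold$structure$dot_bracket)
  }

  target_len <- switch(trig$mode,
    toehold_only = nchar(swt$toehold),
    stem_only = nchar(swt$stem5),
    toehold_stem = nchar(swt$toehold) + nchar(swt$stem5),
    toehold_stem_loop = nchar(swt$toehold) + nchar(swt$stem5) + nchar(swt$loop)
  )
  target_start <- if (trig$mode == "stem_only") nchar(swt$toehold) else 0L
  duplex_fold <- fold_mfe(c(S, trig$sequence), model)
  hp <- duplex_fold$structure$pairs
  nS <- nchar(S)
  # SWT position p must pair trigger position (target_start + target_len - 1 - p)
  expected <- cbind(
    target_start + seq_len(target_len) - 1L,
    nS + target_start + target_len - (target_start + seq_len(target_len) - 1L) - 1L
  )
  hybridized <- if (nrow(hp) == 0) 0 else {
    sum(apply(expected, 1, function(p) any(hp[, 1] == p[1] & hp[, 2] == p[2]))) /
      nrow(expected)
  }
  add("cognate_duplex_mfe", hybridized, hybridized == 1,
      duplex_fold$structure$dot_bracket)

  dplyr::bind_rows(rows)
}
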