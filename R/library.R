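# Greedy assembly of orthogonal SWT libraries and crosstalk auditing.

#' Crosstalk matrix of an SWT/trigger library
#'
#' Predicted activation of every SWT by every trigger (rows = SWTs, columns
#' = triggers) at the screening concentration, plus the three categories of
#' report tubes: each construct alone, all SWTs and triggers pooled in one
#' tube, and every SWT-trigger pair tube.
#'
#' @param swts List of `swt_design` objects.
#' @param triggers List of `trigger_design` objects (same length/order).
#' @param constraints A `design_constraints`.
#' @param model An `energy_model`.
#' @param tubes Also compute the three tube-report categories (slower).
#' @return An object of class `crosstalk_matrix`: list with `activation`
#'   (numeric matrix), `tidy` (long tibble) and `tubes`.
#' @export
crosstalk_matrix <- function(swts, triggers, constraints = design_constraints(),
                             model = energy_model(), tubes = FALSE) {
  stopifnot(length(swts) >= 1, length(triggers) >= 1)
  sn <- vapply(swts, function(s) s$name, character(1))
  tn <- vapply(triggers, function(t) t$name, character(1))
  act <- matrix(NA_real_, length(swts), length(triggers), dimnames = list(sn, tn))
  for (i in seq_along(swts)) {
    for (j in seq_along(triggers)) {
      act[i, j] <- predicted_activation(swts[[i]], triggers[[j]], constraints, model)
    }
  }
  long <- tibble::as_tibble(as.table(act), .name_repair = "minimal")
  names(long) <- c("swt", "trigger", "activation")
  tube_reports <- if (tubes) {
    library_tubes(swts, triggers, constraints, model)
  } else {
    NULL
  }
  structure(
    list(activation = act, tidy = tibble::as_tibble(long), tubes = tube_reports),
    class = "crosstalk_matrix"
  )
}

#' @export
print.crosstalk_matrix <- function(x, ...) {
  cat("<crosstalk_matrix>\n")
  print(round(x$activation, 4))
  invisible(x)
}

# The three report-tube categories: individual constructs, pooled
# everything, and each SWT/trigger pair.
library_tubes <- function(swts, triggers, constraints, model) {
  conc <- constraints$concentration
  strands <- c(
    stats::setNames(
      vapply(swts, swt_transcript, character(1)),
      vapply(swts, function(s) s$name, character(1))
    ),
    stats::setNames(
      vapply(triggers, function(t) t$sequence, character(1)),
      vapply(triggers, function(t) t$name, character(1))
    )
  )
  individual <- purrr::map_dfr(names(strands), function(nm) {
    res <- equilibrium_concentrations(
      tube(strands[nm], concentrations = conc), model
    )
    tibble::tibble(
      construct = nm,
      free_fraction = attr(res, "free_fraction")[[nm]]
    )
  })
  pooled <- equilibrium_concentrations(
    tube(strands, concentrations = conc), model
  )
  pairs <- purrr::map_dfr(seq_along(swts), function(i) {
    purrr::map_dfr(seq_along(triggers), function(j) {
      nm_s <- swts[[i]]$name
      nm_t <- triggers[[j]]$name
      res <- equilibrium_concentrations(
        tube(strands[c(nm_s, nm_t)], concentrations = conc), model
      )
      tibble::tibble(
        swt = nm_s, trigger = nm_t, cognate = (i == j),
        bound_fraction = bound_fraction(res, nm_s, nm_t)
      )
    })
  })
  list(individual = individual, pooled = pooled, pairs = pairs)
}

#' Design a library of mutually orthogonal SWT/trigger pairs
#'
#' Greedy sequential design: candidates (random toehold + random stem from
#' the configured stem space) are drawn, filtered through
#' [check_candidate()], and accepted when the cognate predicted activation
#' reaches `cognate_min_activation` and every cross activation against the
#' already-accepted pairs (both directions) stays at or below
#' `crosstalk_threshold`. The result carries the full crosstalk matrix, the
#' seed, and a snapshot of the constraints for exact reproducibility.
#'
#' @param n Number of orthogonal pairs to design.
#' @param constraints A `design_constraints`.
#' @param model An `energy_model`.
#' @param seed Integer seed; the run is fully reproducible from it.
#' @param name_prefix Prefix for construct names.
#' @param tubes Include the three tube-report categories in the result.
#' @return An object of class `swt_library`.
#' @export
design_library <- function(n, constraints = design_constraints(),
                           model = energy_model(), seed = 1,
                           name_prefix = "S", tubes = FALSE) {
  stopifnot(n >= 1)
  set.seed(seed)
  accepted <- list()
  attempts <- 0L
  budget <- constraints$max_candidates_per_slot
  warned <- character(0)

  while (length(accepted) < n) {
    slot <- length(accepted) + 1L
    slot_attempts <- 0L
    found <- FALSE
    while (slot_attempts < budget) {
      th <- tryCatch(
        sample_toehold(constraints, model, budget = budget - slot_attempts),
        error = function(e) NULL
      )
      if (is.null(th)) break
      slot_attempts <- slot_attempts + attr(th, "attempts")
      stem5 <- sample_stem_arm(constraints$stem_length, constraints$stem_nonGC_pairs)
      repaired <- repair_candidate(as.character(th), stem5, constraints, model)
      if (is.null(repaired)) {
        slot_attempts <- slot_attempts + 400L
        next
      }
      slot_attempts <- slot_attempts + attr(repaired, "steps")
      cand_swt <- swt(
        paste0(name_prefix, slot), toehold = repaired$toehold,
        stem5 = repaired$stem5,
        loop = constraints$loop, polyU_len = constraints$polyU_len,
        toehold_length = constraints$toehold_length
      )
      cand <- candidate_pair(cand_swt, mode = constraints$trigger_mode)
      diag <- check_candidate(cand, constraints, model)
      if (!all(diag$pass)) next
      on_act <- predicted_activation(cand$swt, cand$trigger, constraints, model)
      if (on_act < constraints$cognate_min_activation) next
      cross_ok <- TRUE
      for (acc in accepted) {
        a1 <- predicted_activation(acc$swt, cand$trigger, constraints, model)
        a2 <- predicted_activation(cand$swt, acc$trigger, constraints, model)
        if (a1 > constraints$crosstalk_threshold ||
            a2 > constraints$crosstalk_threshold) {
          cross_ok <- FALSE
          break
        }
      }
      if (!cross_ok) next
      for (acc in accepted) {
        dg <- duplex_dG(cand$trigger$sequence, acc$trigger$sequence, model)
        if (is.finite(dg) && dg < constraints$trigger_duplex_warn_dG) {
          warned <- c(warned, sprintf(
            "trigger-trigger duplex %s/%s dG = %.2f kcal/mol",
            cand$trigger$name, acc$trigger$name, dg
          ))
        }
      }
      cand$diagnostics <- diag
      accepted[[slot]] <- cand
      found <- TRUE
      break
    }
    attempts <- attempts + slot_attempts
    if (!found) {
      partial <- finalize_library(accepted, constraints, model, seed, attempts,
                                  warned, tubes = FALSE)
      rlang::abort(
        sprintf(
          "design budget exhausted at slot %d (%d/%d pairs accepted)",
          slot, length(accepted), n
        ),
        class = "swtdesign_design_error",
        library = partial
      )
    }
  }
  for (w in unique(warned)) warning(w, call. = FALSE)
  finalize_library(accepted, constraints, model, seed, attempts, warned, tubes)
}

finalize_library <- function(accepted, constraints, model, seed, attempts,
                             warnings, tubes) {
  xt <- if (length(accepted) > 0) {
    crosstalk_matrix(
      purrr::map(accepted, "swt"), purrr::map(accepted, "trigger"),
      constraints, model, tubes = tubes
    )
  } else {
    NULL
  }
  structure(
    list(
      pairs = accepted,
      crosstalk = xt,
      constraints = constraints,
      seed = seed,
      attempts = attempts,
      warnings = unique(warnings)
    ),
    class = "swt_library"
  )
}

#' @export
print.swt_library <- function(x, ...) {
  cat(sprintf(
    "<swt_library> %d orthogonal pair(s), seed %d, %d candidate draws\n",
    length(x$pairs), x$seed, x$attempts
  ))
  if (!is.null(x$crosstalk)) print(x$crosstalk)
  invisible(x)
}

#' Multi-tube ensemble defect of a library
#'
#' Aggregates, across the three declared tube categories, the concentration
#' fraction allocated to off-target complexes: in individual tubes the
#' on-target state is the free monomer, in SWT/trigger pair tubes it is the
#' cognate duplex, and in the pooled tube the cognate duplexes. Zero for a
#' perfectly orthogonal library.
#'
#' @param library An `swt_library` (or list of `candidate_pair`s).
#' @param constraints A `design_constraints`.
#' @param model An `energy_model`.
#' @return Non-negative defect score with per-tube breakdown as attribute
#'   `breakdown`.
#' @export
multi_tube_defect <- function(library, constraints = design_constraints(),
                              model = energy_model()) {
  pairs <- if (inherits(library, "swt_library")) library$pairs else library
  if (inherits(library, "swt_library")) constraints <- library$constraints
  swts <- purrr::map(pairs, "swt")
  triggers <- purrr::map(pairs, "trigger")
  conc <- constraints$concentration
  sn <- vapply(swts, function(s) s$name, character(1))
  tn <- vapply(triggers, function(t) t$name, character(1))
  strands <- c(
    stats::setNames(vapply(swts, swt_transcript, character(1)), sn),
    stats::setNames(vapply(triggers, function(t) t$sequence, character(1)), tn)
  )
  cognate <- tibble::tibble(swt = sn, trigger = tn)

  defect_of <- function(result, on_target) {
    # on_target: character vector of complex names that are on-target
    dimers <- dplyr::filter(result, !is.na(.data$species2))
    totals <- attr(result, "totals")
    off <- dplyr::filter(dimers, !(.data$complex %in% on_target))
    per_strand <- vapply(names(totals), function(nm) {
      stoich <- (off$species1 == nm) + (off$species2 == nm)
      sum(stoich * off$concentration_M) / totals[[nm]]
    }, numeric(1))
    sum(per_strand)
  }

  individual <- sum(vapply(names(strands), function(nm) {
    res <- equilibrium_concentrations(tube(strands[nm], conc), model)
    defect_of(res, on_target = character(0))
  }, numeric(1)))

  pair_defect <- sum(vapply(seq_along(pairs), function(i) {
    res <- equilibrium_concentrations(tube(strands[c(sn[i], tn[i])], conc), model)
    defect_of(res, on_target = paste0(sn[i], "·", tn[i]))
  }, numeric(1)))

  pooled_res <- equilibrium_concentrations(tube(strands, conc), model)
  pooled <- defect_of(pooled_res, on_target = paste0(sn, "·", tn))

  structure(
    individual + pair_defect + pooled,
    breakdown = c(individual = individual, pairs = pair_defect, pooled = pooled)
  )
}

#' @describeIn design_library Tidy view of a designed library.
#' @param x An `swt_library`.
#' @param ... Unused.
#' @export
tidy.swt_library <- function(x, ...) {
  purrr::map_dfr(x$pairs, function(p) {
    tibble::tibble(
      swt = p$swt$name,
      trigger = p$trigger$name,
      toehold = p$swt$toehold,
      stem5 = p$swt$stem5,
      loop = p$swt$loop,
      polyU = p$swt$polyU,
      transcript = swt_transcript(p$swt),
      trigger_mode = p$trigger$mode,
      trigger_seq = p$trigger$sequence
    )
  })
}

#' @describeIn design_library One-row library summary.
#' @export
glance.swt_library <- function(x, ...) {
  act <- x$crosstalk$activation
  off <- act
  diag(off) <- NA
  tibble::tibble(
    n_pairs = length(x$pairs),
    min_diagonal = min(diag(act)),
    max_offdiagonal = if (length(x$pairs) > 1) max(off, na.rm = TRUE) else NA_real_,
    seed = x$seed,
    attempts = x$attempts
  )
}

#' Heatmap of a crosstalk matrix
#'
#' @param object A `crosstalk_matrix` or `swt_library`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crosstalk_matrix <- function(object, ...) {
  if (inherits(object, "swt_library")) object <- object$crosstalk
  df <- object$tidy
  ggplot2::ggplot(df, ggplot2::aes(.data$trigger, .data$swt, fill = .data$activation)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$activation)),
                       color = "white", size = 3) +
    ggplot2::scale_fill_gradient(low = "grey15", high = "#2c7fb8", limits = c(0, 1)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(
      x = "trigger RNA", y = "SWT",
      fill = "predicted\nactivation",
      title = "Predicted SWT activation by trigger"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.swt_library <- autoplot.crosstalk_matrix
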