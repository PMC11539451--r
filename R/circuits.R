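# Composition and in-silico evaluation of multilayer SWT circuits.

#' Construct a circuit from explicit layers
#'
#' A circuit is a DAG of switch layers. Each layer carries a switch
#' (`swt_design`), the signal sequence that activates it (its cognate
#' trigger), and an output: either a `trigger_design` consumed downstream or
#' the literal `"reporter"`. Internal signals are matched by sequence
#' identity, not by name. Validation requires exactly one reporter layer,
#' every internal output to feed exactly one downstream switch, acyclicity,
#' and the reporter to be reachable from every external input.
#'
#' @param layers List of layers: each `list(name, swt, input_seq, output)`.
#' @param inputs Named list of external `trigger_design` inputs.
#' @return An object of class `swt_circuit`.
#' @export
circuit <- function(layers, inputs) {
  stopifnot(length(layers) >= 1, length(inputs) >= 1)
  nm <- vapply(layers, function(l) l$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate layer names", call. = FALSE)
  for (l in layers) {
    stopifnot(inherits(l$swt, "swt_design"), is.character(l$input_seq))
    if (!identical(l$output, "reporter") && !inherits(l$output, "trigger_design")) {
      stop("layer output must be a trigger_design or \"reporter\"", call. = FALSE)
    }
  }
  reporters <- vapply(layers, function(l) identical(l$output, "reporter"), logical(1))
  if (sum(reporters) != 1) {
    stop("circuit must have exactly one reporter layer", call. = FALSE)
  }
  # wiring: every internal output must be cognate (by sequence) to exactly
  # one downstream layer's input
  input_seqs <- vapply(layers, function(l) l$input_seq, character(1))
  edges <- list()
  for (i in seq_along(layers)) {
    if (reporters[i]) next
    out_seq <- layers[[i]]$output$sequence
    consumers <- which(input_seqs == out_seq)
    if (length(consumers) == 0) {
      stop(sprintf(
        "wiring error: output of layer '%s' is not cognate to any switch", nm[i]
      ), call. = FALSE)
    }
    if (i %in% consumers) {
      stop(sprintf("cycle error: layer '%s' would trigger itself", nm[i]),
           call. = FALSE)
    }
    for (k in consumers) edges[[length(edges) + 1]] <- c(i, k)
  }
  # acyclicity via repeated removal of source nodes
  if (length(edges) > 0) {
    em <- do.call(rbind, edges)
    remaining <- seq_along(layers)
    repeat {
      has_in <- unique(em[em[, 1] %in% remaining, 2])
      sources <- setdiff(remaining, has_in)
      if (length(sources) == 0) break
      remaining <- setdiff(remaining, sources)
    }
    if (length(remaining) > 0) {
      stop("cycle error: circuit layers form a cycle", call. = FALSE)
    }
  }
  # reporter reachable from every external input
  reach <- function(start_seq) {
    active <- which(input_seqs == start_seq)
    seen <- integer(0)
    while (length(active) > 0) {
      seen <- union(seen, active)
      nxt <- unlist(lapply(active, function(i) {
        if (identical(layers[[i]]$output, "reporter")) return(integer(0))
        which(input_seqs == layers[[i]]$output$sequence)
      }))
      active <- setdiff(nxt, seen)
    }
    any(vapply(seen, function(i) identical(layers[[i]]$output, "reporter"), logical(1)))
  }
  for (inp in inputs) {
    if (!reach(inp$sequence)) {
      stop(sprintf(
        "wiring error: reporter not reachable from input '%s'", inp$name
      ), call. = FALSE)
    }
  }
  structure(
    list(layers = layers, inputs = inputs,
         reporter = nm[reporters]),
    class = "swt_circuit"
  )
}

#' @export
print.swt_circuit <- function(x, ...) {
  cat(sprintf(
    "<swt_circuit> %d switch layer(s), %d input(s), reporter at '%s'\n",
    length(x$layers), length(x$inputs), x$reporter
  ))
  invisible(x)
}

#' Compose a transcriptional cascade
#'
#' Builds a linear cascade from an ordered list of cognate SWT/trigger
#' pairs: layer *i*'s transcript encodes the trigger for layer *i + 1*, the
#' final layer drives the reporter, and the external input is the first
#' pair's trigger. With the input layer counted, `length(pairs) + 1` layers.
#'
#' @param pairs Ordered list of `candidate_pair`s from one library.
#' @return An `swt_circuit`.
#' @export
compose_cascade <- function(pairs) {
  stopifnot(length(pairs) >= 1,
            all(vapply(pairs, inherits, logical(1), "candidate_pair")))
  layers <- lapply(seq_along(pairs), function(i) {
    list(
      name = pairs[[i]]$swt$name,
      swt = pairs[[i]]$swt,
      input_seq = pairs[[i]]$trigger$sequence,
      output = if (i < length(pairs)) pairs[[i + 1]]$trigger else "reporter"
    )
  })
  circuit(layers, inputs = stats::setNames(
    list(pairs[[1]]$trigger), pairs[[1]]$trigger$name
  ))
}

#' Compose a two-input, three-layer OR gate
#'
#' Two converter switches each transcribe the same common signal -- the
#' output switch's cognate trigger -- so the reporter turns on when either
#' external input is present.
#'
#' @param converter_a,converter_b `candidate_pair`s for the two input
#'   branches.
#' @param output `candidate_pair` for the reporter layer.
#' @param emit_a,emit_b Signals emitted by the converters; default to the
#'   output pair's cognate trigger. Distinct emitted signals are a wiring
#'   error.
#' @return An `swt_circuit`.
#' @export
compose_or_gate <- function(converter_a, converter_b, output,
                            emit_a = NULL, emit_b = NULL) {
  for (p in list(converter_a, converter_b, output)) {
    stopifnot(inherits(p, "candidate_pair"))
  }
  emit_a <- emit_a %||% output$trigger
  emit_b <- emit_b %||% output$trigger
  if (!identical(emit_a$sequence, emit_b$sequence)) {
    stop("wiring error: converters emit different signals", call. = FALSE)
  }
  if (converter_a$swt$name == output$swt$name ||
      converter_b$swt$name == output$swt$name) {
    stop("cycle error: converter reuses the output switch", call. = FALSE)
  }
  layers <- list(
    list(name = converter_a$swt$name, swt = converter_a$swt,
         input_seq = converter_a$trigger$sequence, output = emit_a),
    list(name = converter_b$swt$name, swt = converter_b$swt,
         input_seq = converter_b$trigger$sequence, output = emit_b),
    list(name = output$swt$name, swt = output$swt,
         input_seq = output$trigger$sequence, output = "reporter")
  )
  circuit(layers, inputs = stats::setNames(
    list(converter_a$trigger, converter_b$trigger),
    c(converter_a$trigger$name, converter_b$trigger$name)
  ))
}

# Internal: activation of a switch by a raw signal sequence.
signal_activation <- function(swt, signal_seq, constraints, model, cache) {
  key <- paste(swt$name, signal_seq, sep = "|")
  if (!is.null(cache[[key]])) return(cache[[key]])
  trig <- structure(
    list(name = "signal", mode = "toehold_stem", sequence = signal_seq,
         cognate = swt$name),
    class = "trigger_design"
  )
  act <- predicted_activation(swt, trig, constraints, model)
  cache[[key]] <- act
  act
}

#' Evaluate a circuit for one input combination
#'
#' Boolean-threshold forward propagation at equilibrium: a switch layer is
#' ON when any present signal (external input or the output of an ON
#' upstream layer) gives predicted activation at or above `theta_on`; the
#' reporter state is the terminal switch's state. Layers listed in
#' `absent_layers` are left out of the reaction entirely (the combinatorial
#' knockout experiment).
#'
#' @param circ An `swt_circuit`.
#' @param input_presence Named logical vector over the circuit inputs.
#' @param constraints A `design_constraints`.
#' @param model An `energy_model`.
#' @param theta_on Activation threshold for the ON state.
#' @param absent_layers Character vector of layer names to drop.
#' @return One-row tibble: input columns, `reporter` (logical), and a
#'   `layer_state` list column with per-layer activation details.
#' @export
evaluate_circuit <- function(circ, input_presence,
                             constraints = design_constraints(),
                             model = energy_model(), theta_on = 0.5,
                             absent_layers = character(0)) {
  stopifnot(inherits(circ, "swt_circuit"))
  input_names <- names(circ$inputs)
  stopifnot(all(input_names %in% names(input_presence)))
  cache <- attr(circ, "activation_cache")
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  layers <- circ$layers[
    !vapply(circ$layers, function(l) l$name %in% absent_layers, logical(1))
  ]
  signals <- vapply(
    circ$inputs[input_presence[input_names]],
    function(t) t$sequence, character(1)
  )
  state <- stats::setNames(rep(FALSE, length(layers)),
                           vapply(layers, function(l) l$name, character(1)))
  best_act <- stats::setNames(rep(0, length(layers)), names(state))
  repeat {
    changed <- FALSE
    for (i in seq_along(layers)) {
      if (state[i]) next
      for (sig in signals) {
        act <- signal_activation(layers[[i]]$swt, sig, constraints, model, cache)
        best_act[i] <- max(best_act[i], act)
        if (act >= theta_on) {
          state[i] <- TRUE
          changed <- TRUE
          if (!identical(layers[[i]]$output, "reporter")) {
            signals <- union(signals, layers[[i]]$output$sequence)
          }
          break
        }
      }
    }
    if (!changed) break
  }
  reporter_on <- isTRUE(state[circ$reporter])
  out <- tibble::as_tibble(as.list(input_presence[input_names]))
  out$reporter <- reporter_on
  out$layer_state <- list(tibble::tibble(
    layer = names(state), on = unname(state), activation = unname(best_act)
  ))
  out
}

#' Full truth table of a circuit
#'
#' Evaluates [evaluate_circuit()] over all `2^k` combinations of the `k`
#' external inputs.
#'
#' @inheritParams evaluate_circuit
#' @return Tibble with `2^k` rows.
#' @export
truth_table <- function(circ, constraints = design_constraints(),
                        model = energy_model(), theta_on = 0.5,
                        absent_layers = character(0)) {
  stopifnot(inherits(circ, "swt_circuit"))
  input_names <- names(circ$inputs)
  attr(circ, "activation_cache") <- new.env(parent = emptyenv())
  combos <- rev(expand.grid(rep(list(c(FALSE, TRUE)), length(input_names))))
  names(combos) <- input_names
  purrr::map_dfr(seq_len(nrow(combos)), function(r) {
    evaluate_circuit(
      circ, unlist(combos[r, , drop = FALSE]), constraints, model,
      theta_on, absent_layers
    )
  })
}

#' Audit a circuit for pairwise crosstalk
#'
#' Pools every circuit species (switch transcripts, external inputs, and
#' internal signals) in a single tube at the screening concentration and
#' flags every non-cognate strand pair whose duplex sequesters more than
#' `crosstalk_threshold` of either strand.
#'
#' @inheritParams evaluate_circuit
#' @return Tibble of strand pairs with `bound_fraction` and `flagged`; the
#'   cognate switch/trigger duplexes are marked `cognate = TRUE` and never
#'   flagged.
#' @export
circuit_crosstalk_audit <- function(circ, constraints = design_constraints(),
                                    model = energy_model()) {
  stopifnot(inherits(circ, "swt_circuit"))
  strands <- character(0)
  cognate <- list()
  for (l in circ$layers) {
    strands[l$name] <- swt_transcript(l$swt)
  }
  for (inp in circ$inputs) {
    if (!inp$sequence %in% strands) strands[inp$name] <- inp$sequence
  }
  for (l in circ$layers) {
    if (!identical(l$output, "reporter") && !l$output$sequence %in% strands) {
      strands[l$output$name] <- l$output$sequence
    }
  }
  for (l in circ$layers) {
    sig <- names(strands)[strands == l$input_seq][1]
    if (!is.na(sig)) cognate[[length(cognate) + 1]] <- c(l$name, sig)
  }
  res <- equilibrium_concentrations(
    tube(strands, concentrations = constraints$concentration), model
  )
  nm <- names(strands)
  rows <- purrr::map_dfr(seq_along(nm), function(i) {
    purrr::map_dfr(seq.int(i, length(nm)), function(j) {
      bf <- bound_fraction(res, nm[i], nm[j])
      bf2 <- bound_fraction(res, nm[j], nm[i])
      is_cognate <- any(vapply(cognate, function(cg) {
        all(sort(cg) == sort(c(nm[i], nm[j])))
      }, logical(1)))
      tibble::tibble(
        species1 = nm[i], species2 = nm[j],
        bound_fraction = max(bf, bf2),
        cognate = is_cognate,
        flagged = !is_cognate & max(bf, bf2) > constraints$crosstalk_threshold
      )
    })
  })
  rows
}
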