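# Plate-reader fluorescence analysis: background normalization, ON/OFF fold
# changes, Welch's t-tests, orthogonality matrices, and a seeded synthetic
# plate generator.

plate_conditions <- c("ON", "OFF", "BACKGROUND")

#' Validate a plate table
#'
#' A plate table holds one row per well measurement with columns `well`,
#' `construct`, `condition` (`ON`, `OFF` or `BACKGROUND`), `replicate`,
#' `fluorescence` (RFU) and `timepoint` (minutes). Every batch needs at
#' least one `BACKGROUND` row (the no-template control).
#'
#' @param plate A data frame.
#' @return Invisibly, the validated tibble.
#' @export
validate_plate <- function(plate) {
  need <- c("well", "construct", "condition", "replicate", "fluorescence", "timepoint")
  missing <- setdiff(need, names(plate))
  if (length(missing) > 0) {
    stop("plate table lacks columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!all(plate$condition %in% plate_conditions)) {
    stop("condition must be one of ON, OFF, BACKGROUND", call. = FALSE)
  }
  if (!any(plate$condition == "BACKGROUND")) {
    stop("plate has no BACKGROUND (no-template control) rows", call. = FALSE)
  }
  if (!all(is.finite(plate$fluorescence))) {
    stop("non-finite fluorescence values", call. = FALSE)
  }
  invisible(tibble::as_tibble(plate))
}

#' Background-subtracted fluorescence
#'
#' Normalized fluorescence is raw fluorescence minus the background (the
#' no-template control). Negative values are possible and produce a
#' warning rather than being clipped.
#'
#' @param raw Raw fluorescence (RFU).
#' @param background Background fluorescence (RFU), typically the batch
#'   mean of the control reactions.
#' @return Normalized fluorescence (RFU).
#' @examples
#' normalize_fluorescence(1500, 300) # 1200
#' @export
normalize_fluorescence <- function(raw, background) {
  out <- raw - background
  if (any(out < 0)) {
    warning("normalized fluorescence below zero (signal under background)",
            call. = FALSE)
  }
  out
}

#' Welch's t-test
#'
#' Unequal-variance two-sample t-test (Welch-Satterthwaite degrees of
#' freedom, two-sided p), as used to compare fluorescence conditions.
#'
#' @param group_a,group_b Numeric vectors (each length >= 2 with nonzero
#'   variance).
#' @return Tibble with columns `t`, `df`, `p`.
#' @examples
#' welch_t_test(c(1, 2, 3), c(4, 5, 6))
#' @export
welch_t_test <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least two values", call. = FALSE)
  }
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (isTRUE(all.equal(mean(group_a), mean(group_b)))) {
      return(tibble::tibble(t = 0, df = Inf, p = 1))
    }
    stop("degenerate groups: both variances are zero", call. = FALSE)
  }
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  tibble::tibble(
    t = unname(ht$statistic),
    df = unname(ht$parameter),
    p = ht$p.value
  )
}

#' ON/OFF fold change of an SWT construct
#'
#' The batch background (mean of the BACKGROUND rows) is subtracted from
#' every measurement; the fold change is the normalized ON replicate mean
#' divided by the normalized OFF replicate mean. A Welch's t-test compares
#' the normalized ON and OFF replicates. A non-positive normalized OFF mean
#' makes the fold change undefined and raises an error rather than being
#' clipped.
#'
#' @param plate A plate table (see [validate_plate()]).
#' @param construct Construct whose ON rows are used.
#' @param off_construct Construct whose OFF rows define the OFF state;
#'   defaults to `construct`.
#' @param timepoint Endpoint to analyze in minutes (default 120, the 2 h
#'   endpoint).
#' @param method `"ratio_of_means"` (replicate-mean ratio, default) or
#'   `"mean_of_ratios"` (mean of replicate-wise ratios; requires equal
#'   replicate counts).
#' @return A one-row `fold_change_result` tibble: `construct`,
#'   `normalized_on`, `normalized_off`, `fold_change`, `t`, `df`, `p`, and a
#'   `replicates` list column with the per-replicate normalized values.
#' @export
fold_change <- function(plate, construct, off_construct = construct,
                        timepoint = 120,
                        method = c("ratio_of_means", "mean_of_ratios")) {
  method <- match.arg(method)
  plate <- validate_plate(plate)
  at_tp <- plate[plate$timepoint == timepoint, ]
  bg_rows <- at_tp$fluorescence[at_tp$condition == "BACKGROUND"]
  on_rows <- at_tp$fluorescence[at_tp$condition == "ON" & at_tp$construct == construct]
  off_rows <- at_tp$fluorescence[at_tp$condition == "OFF" &
                                   at_tp$construct == off_construct]
  if (length(on_rows) == 0 || length(off_rows) == 0 || length(bg_rows) == 0) {
    stop("ON, OFF and BACKGROUND rows are all required", call. = FALSE)
  }
  bg <- mean(bg_rows)
  on_norm <- withCallingHandlers(
    normalize_fluorescence(on_rows, bg),
    warning = function(w) invokeRestart("muffleWarning")
  )
  off_norm <- withCallingHandlers(
    normalize_fluorescence(off_rows, bg),
    warning = function(w) invokeRestart("muffleWarning")
  )
  mean_off <- mean(off_norm)
  if (mean_off <= 0) {
    stop(sprintf(
      "fold change undefined for '%s': normalized OFF mean is %.3g <= 0",
      construct, mean_off
    ), call. = FALSE)
  }
  fc <- if (method == "ratio_of_means") {
    mean(on_norm) / mean_off
  } else {
    if (length(on_norm) != length(off_norm)) {
      stop("mean_of_ratios needs equal ON/OFF replicate counts", call. = FALSE)
    }
    mean(on_norm / off_norm)
  }
  wt <- tryCatch(
    welch_t_test(on_norm, off_norm),
    error = function(e) tibble::tibble(t = NA_real_, df = NA_real_, p = NA_real_)
  )
  out <- tibble::tibble(
    construct = construct,
    normalized_on = mean(on_norm),
    normalized_off = mean_off,
    fold_change = fc,
    t = wt$t, df = wt$df, p = wt$p,
    replicates = list(tibble::tibble(
      condition = rep(c("ON", "OFF"), c(length(on_norm), length(off_norm))),
      normalized = c(on_norm, off_norm)
    ))
  )
  class(out) <- c("fold_change_result", class(out))
  out
}

#' @describeIn fold_change Tidy per-replicate view of a fold-change result.
#' @param x A `fold_change_result`.
#' @param ... Unused.
#' @export
tidy.fold_change_result <- function(x, ...) {
  tidyr::unnest(
    dplyr::select(tibble::as_tibble(x), "construct", "replicates"),
    "replicates"
  )
}

#' @describeIn fold_change One-row summary (drops the replicate detail).
#' @export
glance.fold_change_result <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x), -"replicates")
}

#' Fold-change orthogonality matrix from a plate
#'
#' Computes the ON/OFF fold change for every SWT/trigger combination in
#' `mapping` and arranges them as an n x n matrix (rows = SWTs, columns =
#' triggers). The OFF state of a switch is its no-trigger condition,
#' identified by `off_construct` (defaulting to the SWT name). Missing
#' combinations stay `NA`.
#'
#' @param plate A plate table.
#' @param mapping Tibble with columns `swt`, `trigger`, `construct` and
#'   optionally `off_construct`.
#' @param timepoint Endpoint in minutes.
#' @return An `orthogonality_matrix`: tibble in long form with attribute
#'   `matrix` (fold changes) and `tests` (Welch statistics).
#' @export
orthogonality_table <- function(plate, mapping, timepoint = 120) {
  stopifnot(all(c("swt", "trigger", "construct") %in% names(mapping)))
  if (!"off_construct" %in% names(mapping)) mapping$off_construct <- mapping$swt
  plate <- validate_plate(plate)
  long <- purrr::pmap_dfr(mapping, function(swt, trigger, construct, off_construct) {
    has_on <- any(plate$condition == "ON" & plate$construct == construct &
                    plate$timepoint == timepoint)
    if (!has_on) {
      return(tibble::tibble(
        swt = swt, trigger = trigger, construct = construct,
        fold_change = NA_real_, t = NA_real_, df = NA_real_, p = NA_real_
      ))
    }
    fc <- fold_change(plate, construct, off_construct, timepoint)
    tibble::tibble(
      swt = swt, trigger = trigger, construct = construct,
      fold_change = fc$fold_change, t = fc$t, df = fc$df, p = fc$p
    )
  })
  swts <- unique(mapping$swt)
  trigs <- unique(mapping$trigger)
  mat <- matrix(NA_real_, length(swts), length(trigs), dimnames = list(swts, trigs))
  for (r in seq_len(nrow(long))) {
    mat[long$swt[r], long$trigger[r]] <- long$fold_change[r]
  }
  structure(long, matrix = mat, class = c("orthogonality_matrix", class(long)))
}

#' Heatmap of a fold-change orthogonality matrix
#'
#' @param object An `orthogonality_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.orthogonality_matrix <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$trigger, .data$swt, fill = .data$fold_change)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$fold_change), "", sprintf("%.1f", .data$fold_change))
    ), color = "white", size = 3) +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(
      x = "trigger RNA", y = "SWT", fill = "fold change",
      title = "ON/OFF fold-change matrix"
    ) +
    ggplot2::theme_minimal()
}

#' Specification for a synthetic fluorescence plate
#'
#' Describes the ground truth a simulated plate should emulate: programmed
#' ON/OFF means per construct, a shared background mean, multiplicative
#' replicate noise (coefficient of variation), and the replicate count.
#' Multiplicative Gaussian noise is a fixture choice reflecting that
#' plate-reader error scales with signal, not a claim about any instrument.
#'
#' @param constructs Tibble with columns `construct`, `on_mean`, `off_mean`.
#' @param background_mean Background fluorescence mean (RFU).
#' @param cv Coefficient of variation of the multiplicative noise.
#' @param n_reps Replicates per condition.
#' @param timepoint Timepoint label for the simulated rows (minutes).
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(constructs, background_mean = 300, cv = 0.05, n_reps = 3,
                     timepoint = 120) {
  stopifnot(all(c("construct", "on_mean", "off_mean") %in% names(constructs)))
  if (any(constructs$on_mean <= background_mean) ||
      any(constructs$off_mean <= background_mean)) {
    stop("programmed means must exceed the background mean", call. = FALSE)
  }
  stopifnot(cv >= 0, n_reps >= 1)
  structure(
    list(
      constructs = tibble::as_tibble(constructs),
      background_mean = background_mean, cv = cv, n_reps = n_reps,
      timepoint = timepoint
    ),
    class = "sim_spec"
  )
}

#' Simulate a fluorescence plate
#'
#' Draws `fluorescence = mean * (1 + cv * z)`, `z ~ N(0, 1)`, for every
#' construct/condition/replicate, plus BACKGROUND rows around the
#' background mean. Fully deterministic given a seed.
#'
#' @param spec A `sim_spec`.
#' @param seed Optional integer seed (uses the current RNG state if `NULL`).
#' @return A plate table (see [validate_plate()]).
#' @export
simulate_plate <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  if (!is.null(seed)) set.seed(seed)
  noise <- function(mu, n) mu * (1 + spec$cv * stats::rnorm(n))
  rows <- purrr::pmap_dfr(spec$constructs, function(construct, on_mean, off_mean, ...) {
    tibble::tibble(
      construct = construct,
      condition = rep(c("ON", "OFF"), each = spec$n_reps),
      replicate = rep(seq_len(spec$n_reps), 2),
      fluorescence = c(noise(on_mean, spec$n_reps), noise(off_mean, spec$n_reps))
    )
  })
  bg <- tibble::tibble(
    construct = "no_template",
    condition = "BACKGROUND",
    replicate = seq_len(spec$n_reps),
    fluorescence = noise(spec$background_mean, spec$n_reps)
  )
  out <- dplyr::bind_rows(rows, bg)
  out$well <- sprintf(
    "%s%02d", LETTERS[(seq_len(nrow(out)) - 1) %/% 24 + 1],
    (seq_len(nrow(out)) - 1) %% 24 + 1
  )
  out$timepoint <- spec$timepoint
  validate_plate(out)
  tibble::as_tibble(out[, c("well", "construct", "condition", "replicate",
                            "fluorescence", "timepoint")])
}
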