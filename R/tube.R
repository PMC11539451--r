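# Dilute-solution test-tube ensembles: complexes of size <= 2 and their
# equilibrium concentrations.

#' Specify a test tube
#'
#' A dilute-solution ensemble of named strands with total concentrations and
#' a maximum complex size of 1 or 2 (monomers and dimers). The default
#' concentration, 10 nM per strand, matches the screening conditions used
#' throughout the design pipeline.
#'
#' @param species Named character vector of RNA sequences.
#' @param concentrations Total strand concentrations in molar; recycled.
#' @param max_complex_size 1 (monomers only) or 2.
#' @param self_dimers Include homodimer complexes (no rotational-symmetry
#'   correction is applied).
#' @return An object of class `tube_spec`.
#' @examples
#' tube(c(a = "ACGUACGU", b = "ACGCAUUA"))
#' @export
tube <- function(species, concentrations = 1e-8, max_complex_size = 2,
                 self_dimers = TRUE) {
  stopifnot(is.character(species), length(species) >= 1)
  if (is.null(names(species)) || any(!nzchar(names(species)))) {
    stop("species must be named", call. = FALSE)
  }
  if (anyDuplicated(names(species))) stop("duplicate species names", call. = FALSE)
  species[] <- vapply(species, as_rna, character(1), warn_lowercase = FALSE)
  concentrations <- rep_len(concentrations, length(species))
  if (any(concentrations <= 0)) stop("concentrations must be > 0", call. = FALSE)
  if (!max_complex_size %in% 1:2) stop("max_complex_size must be 1 or 2", call. = FALSE)
  structure(
    list(
      species = species,
      concentrations = stats::setNames(concentrations, names(species)),
      max_complex_size = as.integer(max_complex_size),
      self_dimers = isTRUE(self_dimers)
    ),
    class = "tube_spec"
  )
}

#' @export
print.tube_spec <- function(x, ...) {
  cat(sprintf(
    "<tube_spec> %d species, max complex size %d\n",
    length(x$species), x$max_complex_size
  ))
  invisible(x)
}

# Association constants (M^-1) for all allowed dimers of a tube.
tube_K_matrix <- function(tube, model) {
  n <- length(tube$species)
  K <- matrix(0, n, n, dimnames = list(names(tube$species), names(tube$species)))
  if (tube$max_complex_size < 2) return(K)
  logQ1 <- vapply(tube$species, function(s) run_dp(s, model)$logQ, numeric(1))
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (i == j && !tube$self_dimers) next
      pf <- partition_function(c(tube$species[[i]], tube$species[[j]]), model)
      if (is.finite(pf$logQ)) {
        K[i, j] <- K[j, i] <- exp(pf$logQ - logQ1[i] - logQ1[j])
      }
    }
  }
  K
}

#' Equilibrium concentrations of a test tube
#'
#' Solves the law-of-mass-action equilibrium for all monomers and allowed
#' dimers: association constants come from the complex partition functions
#' (`K = Q_dimer / (Q_a Q_b)` relative to a 1 M standard state) and the free
#' monomer concentrations satisfy per-strand mass conservation. A damped
#' fixed-point iteration is used (tolerance `1e-12` on the relative mass
#' residual, at most `1e5` iterations).
#'
#' @param tube A `tube_spec`.
#' @param model An `energy_model`.
#' @param tol Relative mass-conservation tolerance.
#' @param max_iter Maximum fixed-point iterations.
#' @return A `tube_result`: tibble with columns `complex`, `species1`,
#'   `species2` (`NA` for monomers), `concentration_M`, plus attributes
#'   `free_fraction` (free monomer fraction per strand) and `mass_residual`.
#' @examples
#' tb <- tube(c(a = "GGGAGGAGGGAGGAGGAGGG", b = "CCCUCCUCCUCCCUCCUCCC"))
#' equilibrium_concentrations(tb)
#' @export
equilibrium_concentrations <- function(tube, model = energy_model(),
                                       tol = 1e-12, max_iter = 1e5) {
  stopifnot(inherits(tube, "tube_spec"))
  n <- length(tube$species)
  ctot <- tube$concentrations
  K <- tube_K_matrix(tube, model)
  x <- ctot
  if (any(K > 0)) {
    Koff <- K
    diag(Koff) <- 0
    mass_of <- function(x) x * (1 + as.vector(Koff %*% x)) + 2 * diag(K) * x^2
    resid_of <- function(x) max(abs(mass_of(x) - ctot) / ctot)
    # damped fixed point to get near the solution
    resid <- resid_of(x)
    for (it in seq_len(max_iter)) {
      denom <- 1 + as.vector(Koff %*% x) + 2 * diag(K) * x
      x <- sqrt(x * (ctot / denom)) # geometric damping keeps iterates positive
      resid <- resid_of(x)
      if (resid < tol || resid < 1e-6) break
    }
    # Newton polish in log-concentration space (quadratic convergence)
    if (resid >= tol) {
      lx <- log(x)
      for (it in seq_len(200)) {
        x <- exp(lx)
        mass <- mass_of(x)
        F <- log(mass / ctot)
        # d mass_i / d log x_j
        J <- Koff * (x %o% x)
        diag(J) <- x + as.vector(Koff %*% x) * x + 4 * diag(K) * x^2
        J <- J / mass # Jacobian of log(mass)
        step <- tryCatch(solve(J, F), error = function(e) NULL)
        if (is.null(step)) break
        alpha <- 1
        repeat {
          lx_new <- lx - alpha * step
          r_new <- resid_of(exp(lx_new))
          if (r_new < resid || alpha < 1e-4) break
          alpha <- alpha / 2
        }
        lx <- lx_new
        resid <- r_new
        if (resid < tol) break
      }
      x <- exp(lx)
    }
    if (resid >= tol) {
      stop(sprintf(
        "equilibrium solver did not converge (residual %.3e)",
        resid
      ), call. = FALSE)
    }
  }
  nm <- names(tube$species)
  rows <- tibble::tibble(
    complex = nm, species1 = nm, species2 = NA_character_,
    concentration_M = as.numeric(x)
  )
  if (tube$max_complex_size >= 2) {
    for (i in seq_len(n)) {
      for (j in i:n) {
        if (K[i, j] == 0) next
        conc <- as.numeric(K[i, j] * x[i] * x[j])
        rows <- dplyr::bind_rows(rows, tibble::tibble(
          complex = paste0(nm[i], "·", nm[j]),
          species1 = nm[i], species2 = nm[j],
          concentration_M = conc
        ))
      }
    }
  }
  structure(
    rows,
    free_fraction = stats::setNames(as.numeric(x) / as.numeric(ctot), nm),
    totals = ctot,
    mass_residual = if (any(K > 0)) resid else 0,
    class = c("tube_result", class(rows))
  )
}

#' Fraction of a strand bound in complexes with another strand
#'
#' @param result A `tube_result`.
#' @param strand Strand whose bound fraction is requested.
#' @param partner Partner strand.
#' @return Fraction of `strand`'s total concentration held in
#'   `strand`-`partner` complexes.
#' @export
bound_fraction <- function(result, strand, partner) {
  stopifnot(inherits(result, "tube_result"))
  dimers <- !is.na(result$species2)
  hit <- dimers & ((result$species1 == strand & result$species2 == partner) |
    (result$species2 == strand & result$species1 == partner))
  stoich <- ifelse(strand == partner, 2, 1)
  bound <- stoich * sum(result$concentration_M[hit])
  bound / attr(result, "totals")[[strand]]
}
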