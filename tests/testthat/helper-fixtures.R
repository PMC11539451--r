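# Shared fixtures: one energy model, random-sequence helpers, and a single
# memoised designed library reused by the designer/circuit/acceptance tests.

test_model <- energy_model()

rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE), collapse = "")

# Boltzmann sum / minimum over the exhaustive enumeration oracle.
oracle_Q <- function(strands, model = test_model) {
  en <- enumerate_structures(strands, model)
  if (nrow(en) == 0) return(list(Q = 0, mfe = Inf))
  list(
    Q = sum(exp(-en$dG / model$RT)),
    mfe = if (length(strands) == 1) min(0, en$dG) else min(en$dG)
  )
}

.fixture_env <- new.env(parent = emptyenv())

# Designed three-pair orthogonal library (expensive; computed once per run).
test_library <- function() {
  if (is.null(.fixture_env$lib3)) {
    .fixture_env$lib3 <- suppressWarnings(
      design_library(3, design_constraints(), test_model, seed = 101)
    )
  }
  .fixture_env$lib3
}

# A structurally valid switch/trigger pair that needs no thermodynamic
# screening (used for wiring-level circuit tests).
toy_pair <- function(name, toehold) {
  s <- swt(name, toehold, stem5 = "CCGG", loop = "GAAA", polyU_len = 6,
           strict = FALSE)
  candidate_pair(s)
}

# Closed-form two-state duplex concentration for totals a, b and K (M^-1).
two_state_duplex <- function(a, b, K) {
  s <- a + b + 1 / K
  (s - sqrt(s^2 - 4 * a * b)) / 2
}

# Closed-form Welch statistics (independent oracle for the t-test).
welch_oracle <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}
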