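test_that("a lone species without self-dimers stays free", {
  m <- test_model
  tb <- tube(c(a = "GGGGAAAACCCC"), 1e-8, self_dimers = FALSE)
  res <- equilibrium_concentrations(tb, m)
  expect_equal(res$concentration_M[res$complex == "a"], 1e-8)
  expect_equal(unname(attr(res, "free_fraction")["a"]), 1)
})

test_that("perfect complements follow the two-state closed form", {
  m <- test_model
  a <- "GGAGGAGGAAGGAGGAGGAA"
  b <- revcomp(a)
  K <- exp(-duplex_dG(a, b, m) / m$RT)
  for (conc in list(c(1e-8, 1e-8), c(2e-8, 5e-9))) {
    tb <- tube(c(a = a, b = b), conc, self_dimers = FALSE)
    res <- equilibrium_concentrations(tb, m)
    got <- res$concentration_M[res$complex == "a·b"]
    want <- two_state_duplex(conc[1], conc[2], K)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("mass is conserved to 1e-9 relative in random tubes", {
  m <- test_model
  set.seed(71)
  for (rep in 1:5) {
    n <- sample(2:4, 1)
    strands <- stats::setNames(
      vapply(seq_len(n), function(i) rand_rna(sample(10:18, 1)), character(1)),
      paste0("s", seq_len(n))
    )
    conc <- stats::setNames(10^stats::runif(n, -9, -7), names(strands))
    res <- equilibrium_concentrations(tube(strands, conc), m)
    expect_true(all(res$concentration_M >= 0))
    for (nm in names(strands)) {
      dimers <- !is.na(res$species2)
      stoich <- (res$species1 == nm) + (res$species2 == nm)
      mass <- res$concentration_M[res$complex == nm] +
        sum((stoich * res$concentration_M)[dimers])
      expect_lt(abs(mass - conc[[nm]]) / conc[[nm]], 1e-9)
    }
  }
})

test_that("doubling all totals never decreases the bound fraction", {
  m <- test_model
  a <- "GGAGGAAGGAAGA"
  b <- revcomp(a)
  f <- vapply(c(1e-9, 2e-9, 8e-9, 1.6e-8), function(c0) {
    res <- equilibrium_concentrations(tube(c(a = a, b = b), c0), m)
    bound_fraction(res, "a", "b")
  }, numeric(1))
  expect_true(all(diff(f) > 0))
})

test_that("tube specifications are validated", {
  expect_error(tube(c("ACGU")), "named")
  expect_error(tube(c(a = "ACGU"), -1), "concentrations")
  expect_error(tube(c(a = "ACGU"), 1e-8, max_complex_size = 3), "max_complex_size")
  expect_error(tube(c(a = "ACGU", a = "GGCC")), "duplicate")
})
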