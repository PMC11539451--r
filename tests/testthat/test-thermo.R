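test_that("structure energies follow the loop decomposition of the bundled table", {
  m <- test_model
  # open chain is the reference state
  expect_equal(structure_energy("ACGUACGU", "........", m), 0)
  # hairpin: three GC/GC stacks plus the 4-nt hairpin penalty
  want <- 3 * m$stack_dG["GC", "GC"] + m$hairpin_dG[["4"]]
  expect_equal(structure_energy("GGGGAAAACCCC", "((((....))))", m), want)
  # fully paired duplex: stacks plus the duplex initiation penalty
  duplex <- structure_energy(c("GGGG", "CCCC"), "((((&))))", m)
  expect_equal(duplex, 3 * m$stack_dG["GC", "GC"] + m$duplex_init_dG)
})

test_that("invalid structures are rejected with informative errors", {
  m <- test_model
  expect_error(db_to_structure("((((....)))"), "unbalanced")
  expect_error(validate_structure("GGAACC", "((..))", m), "hairpin loop")
  expect_error(validate_structure("AAAAAAAA", "((....))", m), "base pair")
  expect_error(
    validate_structure(c("GGGGAAAACCCC", "AAAA"), "((((....))))&....", m),
    "connected"
  )
  # crossing pairs via an explicit pair list
  st <- rna_structure(rbind(c(0, 5), c(2, 8)), 10)
  expect_error(validate_structure("GGGGGUUUUU", st, m), "seudoknot")
})

test_that("folding finds the MFE and reports unstructured chains", {
  m <- test_model
  f <- fold_mfe("AAAAAAAA", m)
  expect_equal(f$dG, 0)
  expect_equal(nrow(f$structure$pairs), 0)
  f2 <- fold_mfe("GGGGAAAACCCC", m)
  expect_equal(f2$structure$dot_bracket, "((((....))))")
  expect_equal(f2$dG, 3 * m$stack_dG["GC", "GC"] + m$hairpin_dG[["4"]])

  expect_true(is_unstructured("AAAAAAAAAA", m))
  expect_identical(nrow(attr(is_unstructured("AAAAAAAAAA", m), "diagnostics")), 0L)
  u <- is_unstructured("GGGGAAAACCCC", m)
  expect_false(u)
  expect_equal(attr(u, "diagnostics")$dot_bracket, "((((....))))")
})

test_that("enumeration lists every valid structure exactly once", {
  m <- test_model
  en <- enumerate_structures("ACGU", m)
  expect_equal(en$dot_bracket, "....") # min hairpin loop forbids all pairs
  en2 <- enumerate_structures("GGGAAACCC", m)
  expect_true("(((...)))" %in% en2$dot_bracket)
  expect_false(anyDuplicated(en2$dot_bracket) > 0)
  # independent recursive counter agrees
  expect_equal(nrow(enumerate_structures("GCGCAAAGCGC", m)),
               count_structures("GCGCAAAGCGC", m))
  set.seed(21)
  for (i in 1:10) {
    s <- rand_rna(sample(6:12, 1))
    expect_equal(nrow(enumerate_structures(s, m)), count_structures(s, m))
  }
  expect_error(enumerate_structures(rand_rna(25), m), "guard")
})

test_that("DP partition function and MFE match exhaustive enumeration", {
  m <- test_model
  expect_equal(partition_function("AAAA", m)$Q, 1)
  set.seed(31)
  for (i in 1:25) {
    s <- rand_rna(sample(6:15, 1))
    or <- oracle_Q(s, m)
    pf <- partition_function(s, m)
    expect_equal(pf$Q, or$Q, tolerance = 1e-9)
    expect_equal(fold_mfe(s, m)$dG, or$mfe, tolerance = 1e-9)
  }
  for (i in 1:15) {
    a <- rand_rna(sample(4:8, 1))
    b <- rand_rna(sample(4:8, 1))
    or <- oracle_Q(c(a, b), m)
    pf <- partition_function(c(a, b), m)
    if (or$Q == 0) {
      expect_equal(pf$Q, 0)
    } else {
      expect_equal(pf$Q, or$Q, tolerance = 1e-9)
      expect_equal(fold_mfe(c(a, b), m)$dG, or$mfe, tolerance = 1e-9)
    }
  }
})

test_that("MFE traceback energies re-evaluate to the reported minimum", {
  m <- test_model
  set.seed(41)
  for (i in 1:15) {
    s <- rand_rna(sample(10:25, 1))
    f <- fold_mfe(s, m)
    expect_equal(structure_energy(s, f$structure, m, check = FALSE), f$dG,
                 tolerance = 1e-9)
  }
})

test_that("the ensemble free energy never exceeds the MFE", {
  m <- test_model
  set.seed(51)
  for (i in 1:10) {
    s <- rand_rna(15)
    expect_lte(partition_function(s, m)$dG, fold_mfe(s, m)$dG + 1e-9)
  }
  for (i in 1:5) {
    a <- rand_rna(8)
    b <- revcomp(a)
    expect_lte(partition_function(c(a, b), m)$dG, fold_mfe(c(a, b), m)$dG + 1e-9)
  }
})

test_that("duplex ensemble energy is symmetric in its strands", {
  m <- test_model
  set.seed(61)
  for (i in 1:6) {
    a <- rand_rna(10)
    b <- rand_rna(10)
    expect_equal(duplex_dG(a, b, m), duplex_dG(b, a, m), tolerance = 1e-9)
  }
})

test_that("cooling enriches structured states for a stable hairpin", {
  s <- "GGGGGAAAACCCCC"
  q37 <- partition_function(s, energy_model(310.15))$Q
  q27 <- partition_function(s, energy_model(300.15))$Q
  expect_gt(q27, q37)
})

test_that("dot-bracket round trips through the pair representation", {
  for (db in c("..((..))..", "((((....))))", "...", "((..((...))..))")) {
    expect_identical(db_to_structure(db)$dot_bracket, db)
  }
  st <- db_to_structure("((((&))))")
  expect_identical(st$lengths, c(4L, 4L))
  expect_identical(st$dot_bracket, "((((&))))")
})
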