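test_that("design constraints validate their invariants", {
  cons <- design_constraints()
  expect_equal(cons$toehold_length, 40L)
  expect_equal(cons$toehold_gc_window, c(0.5, 0.6))
  expect_equal(cons$stem_length, 10L)
  expect_equal(cons$stem_nonGC_pairs, 1L)
  expect_equal(cons$concentration, 1e-8)
  expect_error(
    design_constraints(crosstalk_threshold = 0.95, cognate_min_activation = 0.9),
    "crosstalk_threshold"
  )
})

test_that("toehold sampling is deterministic, in-window, and unstructured", {
  cons <- design_constraints()
  set.seed(42)
  a <- sample_toehold(cons, test_model)
  set.seed(42)
  b <- sample_toehold(cons, test_model)
  expect_identical(as.character(a), as.character(b))
  expect_true(is_unstructured(as.character(a), test_model))

  fast <- design_constraints(require_unstructured_toehold = FALSE)
  set.seed(43)
  draws <- vapply(1:200, function(i) as.character(sample_toehold(fast, test_model)),
                  character(1))
  expect_true(all(nchar(draws) == 40))
  g <- gc_fraction(draws)
  expect_true(all(g >= 0.5 & g <= 0.6))
})

test_that("an exhausted sampling budget raises a design error", {
  cons <- design_constraints(toehold_gc_window = c(0.0, 0.01))
  set.seed(1)
  expect_error(sample_toehold(cons, test_model, budget = 25), "budget")
})

test_that("candidate diagnostics pass for a designed pair and catch defects", {
  lib <- test_library()
  cons <- lib$constraints
  pair <- lib$pairs[[1]]
  diag <- check_candidate(pair, cons, test_model)
  expect_true(all(diag$pass))
  expect_setequal(
    diag$check,
    c("toehold_gc", "toehold_unstructured", "terminator_is_mfe",
      "trigger_linear", "cognate_duplex_mfe")
  )

  # negative control: shuffled trigger no longer hybridizes the target
  set.seed(5)
  shuffled <- paste(sample(seq_chars(pair$trigger$sequence)), collapse = "")
  bad <- pair
  bad$trigger$sequence <- shuffled
  diag_bad <- check_candidate(bad, cons, test_model)
  expect_false(diag_bad$value[diag_bad$check == "cognate_duplex_mfe"] == 1)

  # structured toehold prefix trips the unstructured check
  s_bad <- swt("bad", paste0("GGGGAAAACCCC", substr(pair$swt$toehold, 13, 40)),
               pair$swt$stem5, pair$swt$loop, strict = FALSE)
  diag2 <- check_candidate(candidate_pair(s_bad), cons, test_model)
  expect_false(diag2$pass[diag2$check == "toehold_unstructured"])
})

test_that("predicted activation separates cognate, partial, and unrelated triggers", {
  lib <- test_library()
  cons <- lib$constraints
  s <- lib$pairs[[1]]$swt
  cognate <- predicted_activation(s, lib$pairs[[1]]$trigger, cons, test_model)
  expect_gte(cognate, cons$cognate_min_activation)
  # an unrelated trigger from the same library is inert
  other <- predicted_activation(s, lib$pairs[[2]]$trigger, cons, test_model)
  expect_lte(other, cons$crosstalk_threshold)
  # a non-complementary strand binds nothing
  polyA <- structure(
    list(name = "pA", mode = "toehold_stem", sequence = strrep("A", 50),
         cognate = s$name),
    class = "trigger_design"
  )
  expect_lt(predicted_activation(s, polyA, cons, test_model), 1e-3)
  expect_lt(predicted_activation(s, polyA, cons, test_model, state = "bound"), 0.05)
})

test_that("activation increases with trigger coverage of the switch", {
  lib <- test_library()
  cons <- lib$constraints
  s <- lib$pairs[[1]]$swt
  act <- vapply(c("toehold_only", "stem_only", "toehold_stem"), function(md) {
    predicted_activation(s, trigger(s, md), cons, test_model)
  }, numeric(1))
  expect_lt(act[["toehold_only"]], act[["toehold_stem"]])
  expect_lt(act[["stem_only"]], act[["toehold_stem"]])
})

test_that("crosstalk matrices are square, bounded, and duplicate-consistent", {
  lib <- test_library()
  cons <- lib$constraints
  act <- lib$crosstalk$activation
  expect_equal(dim(act), c(3, 3))
  expect_true(all(act >= 0 & act <= 1))
  # identical trigger listed twice gives identical columns
  xt <- crosstalk_matrix(
    list(lib$pairs[[1]]$swt),
    list(lib$pairs[[1]]$trigger, lib$pairs[[1]]$trigger),
    cons, test_model
  )
  expect_equal(xt$activation[, 1], xt$activation[, 2])
})

test_that("the designed library satisfies its acceptance surface", {
  lib <- test_library()
  cons <- lib$constraints
  act <- lib$crosstalk$activation
  expect_gte(min(diag(act)), cons$cognate_min_activation)
  off <- act
  diag(off) <- NA
  expect_lte(max(off, na.rm = TRUE), cons$crosstalk_threshold)
  # diagonal dominance follows from the two thresholds
  expect_gte(
    min(diag(act)) / max(max(off, na.rm = TRUE), 1e-12),
    cons$cognate_min_activation / cons$crosstalk_threshold
  )
  expect_true(all(vapply(lib$pairs, function(p) all(p$diagnostics$pass), logical(1))))
})

test_that("the multi-tube defect detects a duplicated trigger", {
  lib <- test_library()
  pairs <- lib$pairs[1:2]
  base <- multi_tube_defect(pairs, lib$constraints, test_model)
  clash <- pairs
  clash[[2]]$trigger$sequence <- pairs[[1]]$trigger$sequence
  worse <- multi_tube_defect(clash, lib$constraints, test_model)
  expect_gt(as.numeric(worse), as.numeric(base))
  # permutation invariance
  flipped <- multi_tube_defect(rev(pairs), lib$constraints, test_model)
  expect_equal(as.numeric(flipped), as.numeric(base), tolerance = 1e-6)
})

test_that("the defect is non-negative and reported per tube category", {
  lib <- test_library()
  d <- multi_tube_defect(lib$pairs[1], lib$constraints, test_model)
  expect_gte(as.numeric(d), 0)
  bd <- attr(d, "breakdown")
  expect_named(bd, c("individual", "pairs", "pooled"))
  expect_true(all(bd >= 0))
})
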