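test_that("reverse complement is correct, involutive and length-preserving", {
  expect_equal(revcomp("AAGG"), "CCUU")
  expect_equal(revcomp("GAUC"), "GAUC") # palindromic fixed point
  set.seed(1)
  for (i in 1:100) {
    x <- rand_rna(40)
    expect_identical(revcomp(revcomp(x)), x)
    expect_identical(nchar(revcomp(x)), nchar(x))
  }
})

test_that("alphabet violations are reported with their position", {
  expect_error(revcomp("ACGX"), "position 4")
  expect_error(validate_rna(""), "empty")
})

test_that("RNA coercion transcribes DNA and rejects mixed alphabets", {
  expect_equal(as_rna("ACGT", warn_lowercase = FALSE), "ACGU")
  expect_warning(as_rna("acgu"), "lowercase")
  expect_error(as_rna("ACUT"), "mixes U and T")
})

test_that("GC fraction matches the definition", {
  expect_equal(gc_fraction("GGCC"), 1.0)
  expect_equal(gc_fraction("AUAU"), 0.0)
  expect_equal(gc_fraction("GCAU"), 0.5)
  expect_error(gc_fraction(""), "empty")
})

test_that("SWT assembly derives the 3' stem arm and orders domains", {
  s <- swt("x", toehold = "AAGG", stem5 = "CCGG", loop = "GAAA", polyU_len = 6,
           strict = FALSE)
  expect_equal(s$stem3, "CCGG") # revcomp of CCGG
  expect_equal(swt_transcript(s), paste0("AAGG", "CCGG", "GAAA", "CCGG", "UUUUUU"))
  s2 <- swt("y", "AAGG", stem5 = "GGG", loop = "UUCG", polyU_len = 6, strict = FALSE)
  expect_equal(s2$stem3, "CCC")
})

test_that("SWT constraints are enforced", {
  expect_error(
    swt("x", "AAGG", "CCGG", "GAAA", polyU_len = 5, strict = FALSE),
    "polyU"
  )
  expect_error(swt("x", "AAGG", "CCGG", "GAAA", polyU_len = 6), "toehold length")
  expect_silent(swt("x", strrep("A", 40), "CCGG", "GAAA", polyU_len = 6))
})

test_that("domain coordinates are 0-based half-open and contiguous", {
  s <- swt("x", "AAGG", "CCGG", "GAAA", polyU_len = 6, strict = FALSE)
  d <- swt_domains(s)
  expect_equal(d$start[1], 0)
  expect_equal(d$end, cumsum(nchar(d$seq)))
  expect_equal(d$start[-1], d$end[-5])
  expect_equal(sum(d$end - d$start), nchar(swt_transcript(s)))
})

test_that("trigger derivation covers all four modes", {
  s <- swt("x", "AAGG", "CCGG", "GAAA", polyU_len = 6, strict = FALSE)
  expect_equal(trigger(s, "toehold_stem")$sequence, "CCGGCCUU")
  expect_equal(trigger(s, "toehold_only")$sequence, "CCUU")
  expect_equal(trigger(s, "stem_only")$sequence, "CCGG")
  expect_equal(trigger(s, "toehold_stem_loop")$sequence, "UUUCCCGGCCUU")
  expect_error(trigger(s, "everything"), "arg")
})

test_that("the default-mode trigger hybridizes its target end-to-end", {
  set.seed(7)
  for (i in 1:20) {
    s <- swt("x", rand_rna(12), rand_rna(6), "GAAA", polyU_len = 6, strict = FALSE)
    tr <- trigger(s, "toehold_stem")
    target <- paste0(s$toehold, s$stem5)
    expect_identical(revcomp(tr$sequence), target)
    expect_equal(nchar(tr$sequence), nchar(s$toehold) + nchar(s$stem5))
  }
})
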