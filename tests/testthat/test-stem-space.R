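# Brute-force count of stem duplexes: every 5' arm over {A,C,G,U} defines a
# unique Watson-Crick duplex, so count arms with exactly n_nonGC positions
# in {A, U}.
brute_stem_count <- function(length, n_nonGC) {
  ids <- 0:(4^length - 1)
  n_au <- rep(0L, length(ids))
  x <- ids
  for (k in seq_len(length)) {
    digit <- x %% 4 # 0=A, 1=C, 2=G, 3=U
    n_au <- n_au + (digit == 0 | digit == 3)
    x <- x %/% 4
  }
  sum(n_au == n_nonGC)
}

test_that("stem-space counting matches brute-force enumeration", {
  expect_equal(stem_space_size(7, 0), 128)
  expect_equal(stem_space_size(10, 1), 10240)
  for (L in c(4, 7, 8)) {
    for (k in 0:2) {
      expect_equal(stem_space_size(L, k), brute_stem_count(L, k))
    }
  }
  expect_equal(stem_space_size(10, 1), brute_stem_count(10, 1))
})

test_that("relaxing 7 bp all-GC to 10 bp with one non-GC pair is an 80-fold expansion", {
  expect_identical(stem_space_size(10, 1) / stem_space_size(7, 0), 80)
})

test_that("stem variants respect their length and GC composition", {
  set.seed(3)
  v <- stem_variants(lengths = c(7, 10), gc_fracs = c(0.9, 1.0), n_per = 4)
  expect_true(all(nchar(v$sequence) == v$length))
  all_gc <- v[v$gc_target == 1, ]
  expect_true(all(grepl("^[GC]+$", all_gc$sequence)))
  ninety <- v[v$gc_target == 0.9 & v$length == 10, ]
  n_gc <- nchar(gsub("[^GC]", "", ninety$sequence))
  expect_true(all(n_gc == 9)) # exactly one A/U position
  expect_true(all(abs(v$gc_fraction - v$gc_target) <= 1 / v$length))
})

test_that("stem variant generation is deterministic under a seed", {
  set.seed(11)
  a <- stem_variants(7, 1.0, n_per = 5)
  set.seed(11)
  b <- stem_variants(7, 1.0, n_per = 5)
  expect_identical(a, b)
})
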