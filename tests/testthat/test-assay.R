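make_plate <- function(on, off, bg, construct = "S1", timepoint = 120) {
  tibble::tibble(
    well = sprintf("A%02d", seq_len(length(on) + length(off) + length(bg))),
    construct = c(rep(construct, length(on) + length(off)),
                  rep("no_template", length(bg))),
    condition = c(rep("ON", length(on)), rep("OFF", length(off)),
                  rep("BACKGROUND", length(bg))),
    replicate = c(seq_along(on), seq_along(off), seq_along(bg)),
    fluorescence = c(on, off, bg),
    timepoint = timepoint
  )
}

test_that("background subtraction is plain arithmetic with a negative warning", {
  expect_equal(normalize_fluorescence(1500, 300), 1200)
  expect_equal(normalize_fluorescence(300, 300), 0)
  expect_warning(out <- normalize_fluorescence(100, 300), "below zero")
  expect_equal(out, -200)
})

test_that("fold change is the ratio of background-subtracted means", {
  pl <- make_plate(on = c(1500, 1500, 1500), off = c(400, 400, 400),
                   bg = c(300, 300, 300))
  fc <- fold_change(pl, "S1")
  expect_equal(fc$fold_change, 12) # (1500-300)/(400-300)
  expect_equal(fc$normalized_on, 1200)
  expect_equal(fc$normalized_off, 100)

  # ON == OFF gives exactly 1
  pl1 <- make_plate(c(900, 910, 890), c(900, 910, 890), c(300, 300, 300))
  expect_equal(fold_change(pl1, "S1")$fold_change, 1)

  # invariance under common rescaling of all RFU values
  pl3 <- pl
  pl3$fluorescence <- pl3$fluorescence * 3
  expect_equal(fold_change(pl3, "S1")$fold_change, 12)
})

test_that("a non-positive normalized OFF state is an explicit error", {
  pl <- make_plate(c(1500, 1400, 1450), c(280, 300, 290), c(300, 300, 300))
  expect_error(fold_change(pl, "S1"), "undefined")
})

test_that("the mean-of-ratios alternative is available", {
  pl <- make_plate(c(1300, 1500), c(400, 500), c(300, 300))
  fc <- fold_change(pl, "S1", method = "mean_of_ratios")
  expect_equal(fc$fold_change, mean(c(1000 / 100, 1200 / 200)))
})

test_that("Welch's t-test matches the closed-form oracle", {
  got <- welch_t_test(c(1, 2, 3), c(4, 5, 6))
  want <- welch_oracle(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$t, -3.6742346, tolerance = 1e-6) # -3 / sqrt(2/3)
  expect_equal(got$df, 4, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)

  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  fwd <- welch_t_test(c(1, 2, 3), c(2, 4, 9))
  rev <- welch_t_test(c(2, 4, 9), c(1, 2, 3))
  expect_equal(fwd$t, -rev$t)
  expect_equal(fwd$p, rev$p)

  expect_error(welch_t_test(1, c(1, 2)), "two values")
  expect_error(welch_t_test(c(1, 1), c(2, 2)), "degenerate")
})

test_that("Welch significance agrees with a permutation test on separated groups", {
  set.seed(9)
  a <- rnorm(6, 10, 0.5)
  b <- rnorm(6, 14, 0.5)
  wt <- welch_t_test(a, b)
  pooled <- c(a, b)
  obs <- abs(mean(a) - mean(b))
  perm <- replicate(2000, {
    idx <- sample(12, 6)
    abs(mean(pooled[idx]) - mean(pooled[-idx]))
  })
  p_perm <- mean(perm >= obs)
  expect_lt(wt$p, 0.05)
  expect_lt(p_perm, 0.05)
})

test_that("plate simulation is exact at zero noise and seed-reproducible", {
  spec <- sim_spec(tibble::tibble(construct = "S1", on_mean = 1500, off_mean = 400),
                   background_mean = 300, cv = 0, n_reps = 3)
  pl <- simulate_plate(spec, seed = 1)
  expect_equal(fold_change(pl, "S1")$fold_change, 12)
  spec2 <- sim_spec(tibble::tibble(construct = "S1", on_mean = 1500, off_mean = 400),
                    background_mean = 300, cv = 0.08, n_reps = 3)
  expect_identical(simulate_plate(spec2, seed = 7), simulate_plate(spec2, seed = 7))
  expect_error(
    sim_spec(tibble::tibble(construct = "S1", on_mean = 200, off_mean = 400), 300),
    "exceed the background"
  )
})

test_that("simulated plates recover programmed fold changes without bias", {
  spec <- sim_spec(
    tibble::tibble(construct = "S1", on_mean = 6300, off_mean = 800),
    background_mean = 300, cv = 0.05, n_reps = 3
  )
  folds <- vapply(1:300, function(s) {
    fold_change(simulate_plate(spec, seed = s), "S1")$fold_change
  }, numeric(1))
  expect_equal(mean(folds), 12, tolerance = 0.02)
})

test_that("orthogonality tables mirror the mapping and keep empty cells empty", {
  combos <- tidyr::expand_grid(swt = c("S1", "S2"), trigger = c("T1", "T2"))
  combos$construct <- paste(combos$swt, combos$trigger, sep = "+")
  diag_combo <- with(combos, (swt == "S1" & trigger == "T1") |
                       (swt == "S2" & trigger == "T2"))
  spec <- sim_spec(
    tibble::tibble(
      construct = combos$construct,
      on_mean = ifelse(diag_combo, 300 + 50 * 500, 300 + 1 * 500),
      off_mean = 800
    ),
    background_mean = 300, cv = 0.05, n_reps = 3
  )
  pl <- simulate_plate(spec, seed = 11)
  # the OFF state of each switch is its own no-trigger condition
  mapping <- combos
  mapping$off_construct <- mapping$construct
  ot <- orthogonality_table(pl, mapping)
  mat <- attr(ot, "matrix")
  expect_identical(rownames(mat), c("S1", "S2"))
  expect_identical(colnames(mat), c("T1", "T2"))
  expect_equal(unname(diag(mat)), c(50, 50), tolerance = 0.15)
  expect_equal(unname(c(mat[1, 2], mat[2, 1])), c(1, 1), tolerance = 0.15)

  # missing combination stays an explicit empty cell
  mapping2 <- mapping[-2, ]
  ot2 <- orthogonality_table(pl, mapping2)
  m2 <- attr(ot2, "matrix")
  expect_true(is.na(m2["S1", "T2"]))
  expect_false(anyNA(diag(m2)))
})
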