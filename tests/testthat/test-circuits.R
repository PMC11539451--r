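# Wiring-level tests use toy pairs (no thermodynamics); signal-propagation
# tests use the shared designed library.

test_that("cascades compose with validated wiring", {
  a <- toy_pair("Sa", "AAGGAAGGAAGG")
  b <- toy_pair("Sb", "CCAACCAACCAA")
  casc <- compose_cascade(list(a, b))
  expect_s3_class(casc, "swt_circuit")
  expect_length(casc$layers, 2)
  expect_equal(casc$reporter, "Sb")
  expect_named(casc$inputs, a$trigger$name)
  # a single pair plus its input is a two-layer circuit
  two <- compose_cascade(list(a))
  expect_length(two$layers, 1)
})

test_that("bad wiring is rejected with named junctions", {
  a <- toy_pair("Sa", "AAGGAAGGAAGG")
  b <- toy_pair("Sb", "CCAACCAACCAA")
  # output trigger that no downstream switch consumes
  dangling <- structure(
    list(name = "dangling", mode = "toehold_stem",
         sequence = "GGGGUUUUCCCCAAAA", cognate = "nobody"),
    class = "trigger_design"
  )
  layers <- list(
    list(name = "Sa", swt = a$swt, input_seq = a$trigger$sequence,
         output = dangling),
    list(name = "Sb", swt = b$swt, input_seq = b$trigger$sequence,
         output = "reporter")
  )
  expect_error(circuit(layers, stats::setNames(list(a$trigger), "in_a")),
               "not cognate to any switch")
  # self-triggering layer
  self_layers <- list(
    list(name = "Sa", swt = a$swt, input_seq = a$trigger$sequence,
         output = a$trigger),
    list(name = "Sb", swt = b$swt, input_seq = b$trigger$sequence,
         output = "reporter")
  )
  expect_error(circuit(self_layers, stats::setNames(list(b$trigger), "in_b")),
               "cycle")
})

test_that("OR-gate composition enforces a common signal and distinct switches", {
  a <- toy_pair("Sa", "AAGGAAGGAAGG")
  b <- toy_pair("Sb", "CCAACCAACCAA")
  o <- toy_pair("So", "AACCAAGGAACC")
  og <- compose_or_gate(a, b, o)
  expect_length(og$layers, 3)
  expect_length(og$inputs, 2)
  expect_error(compose_or_gate(a, b, o, emit_a = o$trigger, emit_b = b$trigger),
               "different signals")
  expect_error(compose_or_gate(a, o, o), "cycle")
})

test_that("signals propagate through a designed two-layer cascade", {
  lib <- test_library()
  cons <- lib$constraints
  casc <- compose_cascade(lib$pairs[1])
  off <- evaluate_circuit(casc, stats::setNames(FALSE, names(casc$inputs)),
                          cons, test_model)
  on <- evaluate_circuit(casc, stats::setNames(TRUE, names(casc$inputs)),
                         cons, test_model)
  expect_false(off$reporter)
  expect_true(on$reporter)
  # determinism
  on2 <- evaluate_circuit(casc, stats::setNames(TRUE, names(casc$inputs)),
                          cons, test_model)
  expect_identical(on$reporter, on2$reporter)
  expect_equal(on$layer_state[[1]]$activation, on2$layer_state[[1]]$activation)
})

test_that("the crosstalk audit lists every strand pair exactly once", {
  lib <- test_library()
  cons <- lib$constraints
  casc <- compose_cascade(lib$pairs[1:2])
  aud <- circuit_crosstalk_audit(casc, cons, test_model)
  keys <- paste(pmin(aud$species1, aud$species2), pmax(aud$species1, aud$species2))
  expect_false(anyDuplicated(keys) > 0)
  expect_true(all(!aud$flagged[aud$cognate]))
  # an orthogonal library's circuit is unflagged
  expect_equal(sum(aud$flagged), 0)
})
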