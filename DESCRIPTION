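Package: swtdesign
Title: Design and Analysis of Switchable Transcription Terminator Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for designing orthogonal switchable transcription
    terminators (SWTs) and their trigger RNAs. Provides sequence primitives
    for the SWT architecture (toehold, terminator stem-loop, poly-U tract),
    a self-contained nearest-neighbor RNA thermodynamics engine (minimum
    free energy folding, partition functions for complexes of up to two
    strands, and dilute test-tube equilibrium concentrations), an automated
    multi-tube screening algorithm that assembles libraries of mutually
    orthogonal SWT/trigger pairs, composition and in-silico evaluation of
    multilayer cascade and OR-gate circuits, and analysis of plate-reader
    fluorescence assays (background normalization, ON/OFF fold changes,
    Welch's t-tests, orthogonality matrices) together with a seeded
    synthetic plate-data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    jsonlite,
    yaml,
    generics,
    ggplot2,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
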