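# FASTA / CSV / JSON interfaces and reproducible run reports.

#' Read sequences from FASTA
#'
#' Sequences are converted to canonical RNA on read (DNA `T` becomes `U`,
#' with a message; lowercase is uppercased with a warning; mixing `U` and
#' `T` in one record is an error).
#'
#' @param path FASTA file.
#' @return Tibble with columns `name`, `description`, `sequence`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  full <- names(set)
  name <- sub("\\s.*$", "", full)
  description <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  raw <- as.character(set)
  if (any(grepl("T", toupper(raw), fixed = TRUE))) {
    message("DNA input detected: converting T -> U")
  }
  tibble::tibble(
    name = name,
    description = description,
    sequence = vapply(raw, as_rna, character(1), USE.NAMES = FALSE)
  )
}

#' Write sequences to FASTA
#'
#' @param x Tibble with columns `name`, `sequence` and optionally
#'   `description`, or a named character vector.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x) && !is.null(names(x))) {
    x <- tibble::tibble(name = names(x), description = "", sequence = unname(x))
  }
  stopifnot(all(c("name", "sequence") %in% names(x)))
  desc <- if ("description" %in% names(x)) x$description else ""
  header <- ifelse(nzchar(desc), paste(x$name, desc), x$name)
  set <- Biostrings::BStringSet(x$sequence)
  names(set) <- header
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

# Domain annotation string for a FASTA description, 0-based half-open.
swt_annotation <- function(swt) {
  d <- swt_domains(swt)
  paste(sprintf("%s=%d:%d", d$domain, d$start, d$end), collapse = ";")
}

# Rebuild an swt_design from a transcript and its annotation string.
swt_from_annotation <- function(name, sequence, annotation) {
  fields <- strsplit(strsplit(annotation, ";", fixed = TRUE)[[1]], "=|:")
  coords <- stats::setNames(
    lapply(fields, function(f) as.integer(f[2:3])),
    vapply(fields, `[`, character(1), 1)
  )
  dom <- function(nm) substr(sequence, coords[[nm]][1] + 1, coords[[nm]][2])
  swt(
    name, toehold = dom("toehold"), stem5 = dom("stem5"), loop = dom("loop"),
    polyU_len = coords[["polyU"]][2] - coords[["polyU"]][1],
    toehold_length = coords[["toehold"]][2] - coords[["toehold"]][1]
  )
}

#' Write a designed library to a directory
#'
#' Emits `swts.fasta` (domain annotations in the description),
#' `triggers.fasta` (mode and cognate switch in the description),
#' `crosstalk.csv` (long-form activation matrix) and `report.json`
#' (constraints snapshot, seed, defect breakdown, diagnostics). Output is
#' byte-deterministic for a given library.
#'
#' @param library An `swt_library`.
#' @param dir Output directory (created if needed).
#' @param defect Optionally precomputed [multi_tube_defect()] score.
#' @return Invisibly, the directory.
#' @export
write_library <- function(library, dir, defect = NULL) {
  stopifnot(inherits(library, "swt_library"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  swts <- tibble::tibble(
    name = vapply(library$pairs, function(p) p$swt$name, character(1)),
    description = vapply(library$pairs, function(p) swt_annotation(p$swt), character(1)),
    sequence = vapply(library$pairs, function(p) swt_transcript(p$swt), character(1))
  )
  trigs <- tibble::tibble(
    name = vapply(library$pairs, function(p) p$trigger$name, character(1)),
    description = vapply(library$pairs, function(p) {
      sprintf("mode=%s;cognate=%s", p$trigger$mode, p$trigger$cognate)
    }, character(1)),
    sequence = vapply(library$pairs, function(p) p$trigger$sequence, character(1))
  )
  write_fasta(swts, file.path(dir, "swts.fasta"))
  write_fasta(trigs, file.path(dir, "triggers.fasta"))
  utils::write.csv(library$crosstalk$tidy, file.path(dir, "crosstalk.csv"),
                   row.names = FALSE)
  report <- list(
    seed = library$seed,
    attempts = library$attempts,
    n_pairs = length(library$pairs),
    constraints = unclass(library$constraints),
    defect = if (!is.null(defect)) as.numeric(defect) else NULL,
    warnings = library$warnings,
    diagnostics = lapply(library$pairs, function(p) {
      stats::setNames(as.list(p$diagnostics$pass), p$diagnostics$check)
    })
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a designed library back from a directory
#'
#' Rebuilds the SWT and trigger objects from the annotated FASTA files
#' written by [write_library()]; the crosstalk matrix can then be
#' recomputed from sequences and constraints alone.
#'
#' @param dir Directory written by [write_library()].
#' @return List with `pairs` (list of `candidate_pair`) and `report`.
#' @export
read_library <- function(dir) {
  swts <- read_fasta(file.path(dir, "swts.fasta"))
  trigs <- read_fasta(file.path(dir, "triggers.fasta"))
  report <- jsonlite::read_json(file.path(dir, "report.json"))
  pairs <- purrr::map(seq_len(nrow(swts)), function(i) {
    s <- swt_from_annotation(swts$name[i], swts$sequence[i], swts$description[i])
    meta <- strsplit(trigs$description[i], ";", fixed = TRUE)[[1]]
    mode <- sub("^mode=", "", meta[grepl("^mode=", meta)])
    tr <- structure(
      list(name = trigs$name[i], mode = mode, sequence = trigs$sequence[i],
           cognate = s$name),
      class = "trigger_design"
    )
    candidate_pair(s, tr)
  })
  list(pairs = pairs, report = report)
}

#' Write or read design constraints as a config file
#'
#' JSON or YAML is chosen by the file extension; the round trip is
#' lossless.
#'
#' @param constraints A `design_constraints`.
#' @param path Config file (`.json`, `.yml` or `.yaml`).
#' @return `read_design_config()` returns a `design_constraints`.
#' @export
write_design_config <- function(constraints, path) {
  stopifnot(inherits(constraints, "design_constraints"))
  x <- unclass(constraints)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_design_config
#' @export
read_design_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(design_constraints, x)
}

#' Write a machine-readable run report
#'
#' Every pipeline invocation can record a JSON report carrying the package
#' version, the command, the resolved seed, a hash of the configuration and
#' digests of the produced files, so that a run is exactly reproducible
#' from `(inputs, config, seed)`.
#'
#' @param command Command name (e.g. `"design"`).
#' @param inputs Character vector of input paths (may be empty).
#' @param outputs Character vector of produced files.
#' @param config A `design_constraints` or plain list.
#' @param seed Integer seed used.
#' @param path Report destination (JSON).
#' @return Invisibly, the report list.
#' @export
run_report <- function(command, inputs, outputs, config, seed, path) {
  cfg <- if (inherits(config, "design_constraints")) unclass(config) else config
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  report <- list(
    tool = "swtdesign",
    version = as.character(utils::packageVersion("swtdesign")),
    command = command,
    seed = as.integer(seed),
    config = cfg,
    config_hash = NA_character_,
    inputs = as.list(inputs),
    outputs = lapply(stats::setNames(outputs, basename(outputs)), function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
  )
  report$config_hash <- digest_string(as.character(cfg_json))
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}

# md5 of a string (via a temporary file; avoids extra dependencies)
digest_string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(x, tf)
  unname(tools::md5sum(tf))
}

#' Validate a run report
#'
#' Checks the minimal report schema and, optionally, that the recorded
#' output digests still match the files on disk.
#'
#' @param path Report JSON.
#' @param check_digests Re-hash the outputs and compare.
#' @return Invisibly `TRUE` (errors otherwise).
#' @export
validate_run_report <- function(path, check_digests = FALSE) {
  rep <- jsonlite::read_json(path)
  need <- c("tool", "version", "command", "seed", "config", "config_hash", "outputs")
  missing <- setdiff(need, names(rep))
  if (length(missing) > 0) {
    stop("run report lacks fields: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (check_digests) {
    for (o in rep$outputs) {
      if (!file.exists(o$path)) stop("missing output: ", o$path, call. = FALSE)
      if (unname(tools::md5sum(o$path)) != o$md5) {
        stop("digest mismatch for ", o$path, call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Read or write a plate table as CSV
#'
#' @param plate A plate table.
#' @param path CSV file.
#' @return `read_plate()` returns a validated plate tibble.
#' @export
write_plate <- function(plate, path) {
  validate_plate(plate)
  utils::write.csv(plate, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plate
#' @export
read_plate <- function(path) {
  validate_plate(utils::read.csv(path, stringsAsFactors = FALSE))
}
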