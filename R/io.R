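#' Read protein sequences from FASTA
#'
#' Multi-record, wrapped-line FASTA via Biostrings. The identifier is the
#' first whitespace-delimited token of the header; record order is
#' preserved.
#'
#' @param path FASTA file path.
#' @return A tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) abort("FASTA file contains no records")
  out <- tibble::tibble(
    id = stringr::word(names(seqs), 1),
    sequence = unname(as.character(seqs)))
  if (any(!nzchar(out$sequence))) {
    abort(sprintf("record '%s' has an empty sequence",
                  out$id[!nzchar(out$sequence)][1]))
  }
  out
}

#' Write protein sequences to FASTA
#'
#' @param proteins Tibble with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  set <- Biostrings::AAStringSet(setNames(proteins$sequence, proteins$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a fragment or identification table as TSV
#'
#' @param table A tibble (e.g. from [fragment_conjugate()] or
#'   [search_dia()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(table, path) {
  drop <- names(table)[vapply(table, is.list, logical(1))]
  readr::write_tsv(table[setdiff(names(table), drop)], path)
  invisible(path)
}

#' Read/write an MRM transition list (CSV)
#'
#' The exchange format between transition design and quantification:
#' columns `transition_id`, `peptide_id`, `precursor_mz`, `precursor_z`,
#' `product_series`, `product_index`, `product_z`, `product_mz`,
#' `isotope`.
#'
#' @param transitions An [design_transitions()] tibble.
#' @param path File path.
#' @return `write_transitions_csv()` returns `path` invisibly;
#'   `read_transitions_csv()` returns an `mrm_transitions` tibble.
#' @export
write_transitions_csv <- function(transitions, path) {
  readr::write_csv(transitions, path)
  invisible(path)
}

#' @rdname write_transitions_csv
#' @export
read_transitions_csv <- function(path) {
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      transition_id = readr::col_character(),
      peptide_id = readr::col_character(),
      precursor_mz = readr::col_double(),
      precursor_z = readr::col_integer(),
      product_series = readr::col_character(),
      product_index = readr::col_integer(),
      product_z = readr::col_integer(),
      product_mz = readr::col_double(),
      isotope = readr::col_character()))
  class(out) <- unique(c("mrm_transitions", class(out)))
  out
}

#' Read/write MRM chromatograms as JSON lines
#'
#' One object per trace with keys `transition_id`, `run_id`, `time`,
#' `intensity`; the simulator's native chromatogram dialect.
#'
#' @param chromatograms Tibble with `transition_id`, `run_id`, `time`
#'   (list), `intensity` (list).
#' @param path File path.
#' @return `write_chromatograms_jsonl()` returns `path` invisibly;
#'   `read_chromatograms_jsonl()` returns the chromatogram tibble.
#' @export
write_chromatograms_jsonl <- function(chromatograms, path) {
  lines <- vapply(seq_len(nrow(chromatograms)), function(i) {
    as.character(jsonlite::toJSON(
      list(transition_id = chromatograms$transition_id[i],
           run_id = chromatograms$run_id[i],
           time = chromatograms$time[[i]],
           intensity = chromatograms$intensity[[i]]),
      auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_chromatograms_jsonl
#' @export
read_chromatograms_jsonl <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) abort("empty chromatogram file")
  rows <- lapply(seq_along(lines), function(i) {
    r <- jsonlite::fromJSON(lines[i])
    if (is.null(r$transition_id) || is.null(r$time)) {
      abort(sprintf("trace %d: missing transition_id or time", i))
    }
    tibble::tibble(transition_id = r$transition_id,
                   run_id = r$run_id %||% NA_character_,
                   time = list(as.numeric(r$time)),
                   intensity = list(as.numeric(r$intensity)))
  })
  dplyr::bind_rows(rows)
}

.known_config_keys <- c(
  "missed_cleavages", "remnant", "scheme_start", "scheme_width",
  "scheme_end", "ms1_tol_ppm", "ms2_tol_ppm", "min_codetected", "rt_tol_s",
  "charge_range", "fragment_max_charge", "score_floor", "apex_tol_s",
  "boundary_frac", "n_transitions", "precursor_charge", "seed")

#' Read and validate a pipeline configuration (YAML)
#'
#' A single configuration file drives every pipeline stage. Unknown keys
#' are rejected; omitted keys fall back to the package defaults.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return A named list with all keys populated.
#' @export
read_config <- function(path = NULL) {
  defaults <- list(
    missed_cleavages = 2, remnant = sumo1_remnant(),
    scheme_start = 600, scheme_width = 25, scheme_end = 1250,
    ms1_tol_ppm = 15, ms2_tol_ppm = 25, min_codetected = 5,
    rt_tol_s = NULL, charge_range = 2:5, fragment_max_charge = 2,
    score_floor = 0.3, apex_tol_s = 5, boundary_frac = 0.05,
    n_transitions = 4, precursor_charge = 3, seed = 1)
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  bad <- setdiff(names(user), .known_config_keys)
  if (length(bad) > 0) {
    abort(paste("unknown configuration key(s):", paste(bad, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, user)
  stopifnot(cfg$missed_cleavages >= 0, cfg$scheme_width > 0,
            cfg$ms1_tol_ppm >= 0, cfg$ms2_tol_ppm >= 0,
            cfg$score_floor >= 0, cfg$score_floor <= 1)
  cfg
}

#' Write a pipeline configuration (YAML)
#'
#' @param config A configuration list (see [read_config()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}
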