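# A spectrum run is a tibble with one row per spectrum:
#   cycle, ms_level, rt_s, window_id (NA for MS1), window_low, window_high,
#   mz (list), intensity (list)
# plus a `scheme` attribute (the swath_scheme). The constructor enforces
# the acquisition invariants.

#' Assemble and validate a DIA spectrum run
#'
#' Checks the cycled-acquisition invariants: every cycle holds exactly one
#' MS1 spectrum and exactly one MS2 spectrum per isolation window of the
#' scheme; retention times increase strictly across cycles; peak arrays are
#' equal-length with non-negative intensities.
#'
#' @param spectra A tibble with columns `cycle`, `ms_level`, `rt_s`,
#'   `window_id`, `window_low`, `window_high`, `mz` (list column),
#'   `intensity` (list column).
#' @param scheme The [swath_scheme()] the run was acquired with.
#' @return The validated tibble with class `spectrum_run` and a `scheme`
#'   attribute.
#' @export
as_spectrum_run <- function(spectra, scheme) {
  need <- c("cycle", "ms_level", "rt_s", "window_id", "window_low",
            "window_high", "mz", "intensity")
  if (!all(need %in% names(spectra))) {
    abort(paste("spectrum table missing column(s):",
                paste(setdiff(need, names(spectra)), collapse = ", ")))
  }
  spectra <- tibble::as_tibble(spectra)
  len_ok <- purrr::map2_lgl(spectra$mz, spectra$intensity,
                            function(m, i) length(m) == length(i))
  if (!all(len_ok)) abort("mz and intensity arrays must be equal length")
  if (any(purrr::map_lgl(spectra$intensity, function(i) any(i < 0)))) {
    abort("intensities must be >= 0")
  }
  for (cy in unique(spectra$cycle)) {
    sub <- spectra[spectra$cycle == cy, ]
    if (sum(sub$ms_level == 1) != 1) {
      abort(sprintf("cycle %d: expected exactly one MS1 spectrum", cy))
    }
    got <- sort(sub$window_id[sub$ms_level == 2])
    want <- scheme$window_id
    missing <- setdiff(want, got)
    if (length(missing) > 0) {
      abort(sprintf("cycle %d: missing MS2 spectrum for window %s",
                    cy, paste(missing, collapse = ", ")))
    }
    if (length(got) != length(want) || anyDuplicated(got)) {
      abort(sprintf("cycle %d: duplicated MS2 window", cy))
    }
  }
  ms1 <- spectra[spectra$ms_level == 1, ]
  cyc_rt <- ms1$rt_s[order(ms1$cycle)]
  if (any(diff(cyc_rt) <= 0)) {
    abort("retention times must strictly increase across cycles")
  }
  attr(spectra, "scheme") <- scheme
  class(spectra) <- unique(c("spectrum_run", class(spectra)))
  spectra
}

#' @export
print.spectrum_run <- function(x, ...) {
  sch <- attr(x, "scheme")
  cat(sprintf("<spectrum_run> %d cycles x (MS1 + %d windows), rt %.1f-%.1f s\n",
              length(unique(x$cycle)), nrow(sch), min(x$rt_s), max(x$rt_s)))
  NextMethod()
}

.jsonl_spectrum <- function(row) {
  obj <- list(ms_level = row$ms_level, rt_s = row$rt_s)
  if (row$ms_level == 2) {
    obj$window_low <- row$window_low
    obj$window_high <- row$window_high
  }
  obj$mz <- row$mz[[1]]
  obj$intensity <- row$intensity[[1]]
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
}

#' Write a spectrum run as JSON lines
#'
#' The package's native spectra dialect: one JSON object per line per
#' spectrum with keys `ms_level`, `rt_s`, `window_low`/`window_high` (MS2
#' only), `mz`, `intensity`. Writing is deterministic: the same run always
#' produces byte-identical output.
#'
#' @param run A [as_spectrum_run()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra_jsonl <- function(run, path) {
  ord <- order(run$cycle, run$ms_level, run$window_id, na.last = FALSE)
  run <- run[ord, ]
  lines <- vapply(seq_len(nrow(run)),
                  function(i) as.character(.jsonl_spectrum(run[i, ])),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read spectra into a validated run
#'
#' Supports the package's JSON-lines dialect and centroided mzML (read
#' through the mzR package). Cycle structure is inferred from the spectrum
#' order (each MS1 opens a cycle) and window assignment from the
#' per-spectrum isolation bounds; the result is validated with
#' [as_spectrum_run()].
#'
#' @param path Input file.
#' @param dialect `"jsonl"` or `"mzml"`.
#' @param scheme Optional [swath_scheme()]; inferred from the isolation
#'   bounds present in the file when omitted.
#' @return A `spectrum_run`.
#' @export
read_spectra <- function(path, dialect = c("jsonl", "mzml"), scheme = NULL) {
  dialect <- match.arg(dialect)
  raw <- switch(dialect,
                jsonl = .read_spectra_jsonl(path),
                mzml = .read_spectra_mzml(path))
  if (is.null(scheme)) {
    ms2 <- raw[raw$ms_level == 2, ]
    wins <- dplyr::distinct(ms2[c("window_low", "window_high")])
    wins <- dplyr::arrange(wins, .data$window_low)
    scheme <- tibble::tibble(window_id = seq_len(nrow(wins)),
                             low = wins$window_low, high = wins$window_high,
                             short = FALSE)
    class(scheme) <- c("swath_scheme", class(scheme))
  }
  key <- paste(scheme$low, scheme$high)
  raw$window_id <- ifelse(
    raw$ms_level == 2,
    scheme$window_id[match(paste(raw$window_low, raw$window_high), key)],
    NA_integer_)
  if (any(raw$ms_level == 2 & is.na(raw$window_id))) {
    bad <- which(raw$ms_level == 2 & is.na(raw$window_id))[1]
    abort(sprintf("spectrum %d: isolation bounds do not match the scheme", bad))
  }
  raw$cycle <- cumsum(raw$ms_level == 1)
  if (any(raw$cycle == 0)) abort("file does not start with an MS1 spectrum")
  as_spectrum_run(raw, scheme)
}

.read_spectra_jsonl <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) abort("empty spectra file")
  recs <- lapply(lines, jsonlite::fromJSON)
  rows <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    if (is.null(r$ms_level) || is.null(r$rt_s)) {
      abort(sprintf("spectrum %d: missing ms_level or rt_s", i))
    }
    if (r$ms_level == 2 && (is.null(r$window_low) || is.null(r$window_high))) {
      abort(sprintf("spectrum %d: MS2 spectrum lacks isolation bounds", i))
    }
    tibble::tibble(
      ms_level = as.integer(r$ms_level), rt_s = as.numeric(r$rt_s),
      window_low = as.numeric(r$window_low %||% NA_real_),
      window_high = as.numeric(r$window_high %||% NA_real_),
      mz = list(as.numeric(r$mz)), intensity = list(as.numeric(r$intensity)))
  })
  dplyr::bind_rows(rows)
}

.read_spectra_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    abort("reading mzML requires the mzR package")
  }
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  hd <- mzR::header(handle)
  pk <- mzR::peaks(handle)
  if (is.matrix(pk)) pk <- list(pk)
  n <- nrow(hd)
  ms2 <- hd$msLevel == 2
  lo <- rep(NA_real_, n)
  hi <- rep(NA_real_, n)
  if (any(ms2)) {
    tgt <- hd$isolationWindowTargetMZ
    lo[ms2] <- tgt[ms2] - hd$isolationWindowLowerOffset[ms2]
    hi[ms2] <- tgt[ms2] + hd$isolationWindowUpperOffset[ms2]
    if (anyNA(lo[ms2]) || anyNA(hi[ms2])) {
      bad <- which(ms2 & (is.na(lo) | is.na(hi)))[1]
      abort(sprintf("spectrum %d: MS2 spectrum lacks isolation bounds", bad))
    }
  }
  tibble::tibble(
    ms_level = as.integer(hd$msLevel), rt_s = as.numeric(hd$retentionTime),
    window_low = lo, window_high = hi,
    mz = purrr::map(pk, function(m) as.numeric(m[, 1])),
    intensity = purrr::map(pk, function(m) as.numeric(m[, 2])))
}
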