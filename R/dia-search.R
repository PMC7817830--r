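#' Default DIA search settings
#'
#' Tolerances and thresholds for the three-stage identification procedure.
#' The instrument class modeled here motivates 15 ppm at MS1 and 25 ppm at
#' MS2; `min_codetected` (diagnostic ions that must co-elute) and
#' `score_floor` (minimum matched fragment fraction) control specificity.
#'
#' @param ms1_tol_ppm MS1 precursor mass tolerance (ppm).
#' @param ms2_tol_ppm MS2 fragment/diagnostic tolerance (ppm).
#' @param min_codetected Minimum diagnostic ions sharing an apex.
#' @param rt_tol_s Apex co-elution tolerance (s); `NULL` = one cycle period.
#' @param charge_range Precursor charges tried during deconvolution.
#' @param fragment_max_charge Highest fragment charge emitted for matching.
#' @param score_floor Minimum matched fraction for an accepted record.
#' @param missed_cleavages Missed cleavages allowed in the digest.
#' @return A named list of settings.
#' @export
dia_settings <- function(ms1_tol_ppm = 15, ms2_tol_ppm = 25,
                         min_codetected = 5, rt_tol_s = NULL,
                         charge_range = 2:5, fragment_max_charge = 2,
                         score_floor = 0.3, missed_cleavages = 2) {
  list(ms1_tol_ppm = ms1_tol_ppm, ms2_tol_ppm = ms2_tol_ppm,
       min_codetected = min_codetected, rt_tol_s = rt_tol_s,
       charge_range = charge_range,
       fragment_max_charge = fragment_max_charge,
       score_floor = score_floor, missed_cleavages = missed_cleavages)
}

.cycle_period <- function(run) {
  rts <- sort(run$rt_s[run$ms_level == 1])
  if (length(rts) < 2) return(1)
  stats::median(diff(rts))
}

#' Extract an ion chromatogram from a DIA run
#'
#' Per cycle, sums the intensity of all peaks within a ppm tolerance of the
#' target m/z, in either the MS1 spectra or one isolation window's MS2
#' spectra. Cycles with no matching peak contribute zero.
#'
#' @param run A `spectrum_run`.
#' @param target_mz Target m/z.
#' @param tol_ppm Tolerance (ppm); 0 keeps exact matches only.
#' @param window Window id, or `NULL`/"MS1" for the MS1 level.
#' @return A tibble of class `xic_trace` with columns `cycle`, `rt_s`,
#'   `intensity` (one row per cycle), and attributes `target_mz`,
#'   `tol_ppm`, `window`.
#' @export
extract_xic <- function(run, target_mz, tol_ppm, window = NULL) {
  if (nrow(run) == 0) abort("empty run")
  if (is.null(window) || identical(window, "MS1")) {
    sub <- run[run$ms_level == 1, ]
  } else {
    sub <- run[run$ms_level == 2 & !is.na(run$window_id) &
                 run$window_id == window, ]
    if (nrow(sub) == 0) abort(sprintf("window %s not present in run", window))
  }
  half <- target_mz * tol_ppm * 1e-6
  out <- tibble::tibble(
    cycle = sub$cycle, rt_s = sub$rt_s,
    intensity = purrr::map2_dbl(sub$mz, sub$intensity, function(m, i) {
      sum(i[abs(m - target_mz) <= half])
    }))
  out <- dplyr::arrange(out, .data$cycle)
  attr(out, "target_mz") <- target_mz
  attr(out, "tol_ppm") <- tol_ppm
  attr(out, "window") <- if (is.null(window)) "MS1" else window
  class(out) <- c("xic_trace", class(out))
  out
}

# indices of strictly positive local maxima (plateau-tolerant at edges)
.local_apexes <- function(y) {
  n <- length(y)
  if (n == 0) return(integer())
  left <- c(-Inf, y[-n])
  right <- c(y[-1], -Inf)
  which(y > 0 & y >= left & y >= right)
}

#' Stage 1: screen isolation windows with remnant diagnostic ions
#'
#' For every window, extracts one chromatogram per diagnostic ion and
#' reports (window, retention time) candidates where at least
#' `min_codetected` diagnostic traces show a local apex within `rt_tol_s`
#' of a common apex. Candidates are ordered by co-detected count, then
#' summed apex intensity; overlapping candidates within a window are
#' merged into the strongest.
#'
#' @param run A `spectrum_run`.
#' @param diagnostics A [diagnostic_ion_set()] tibble.
#' @param tol_ppm Extraction tolerance (ppm).
#' @param min_codetected Minimum co-eluting diagnostic ions (k).
#' @param rt_tol_s Co-elution tolerance; `NULL` = one cycle period.
#' @return A tibble with columns `window_id`, `apex_rt`, `co_detected`,
#'   `summed_intensity`, `ions` (list of co-detected ion names).
#' @export
screen_diagnostics <- function(run, diagnostics, tol_ppm = 25,
                               min_codetected = 5, rt_tol_s = NULL) {
  if (nrow(diagnostics) == 0) abort("diagnostic set is empty")
  if (min_codetected < 1 || min_codetected > nrow(diagnostics)) {
    abort("min_codetected must be between 1 and the diagnostic set size")
  }
  rt_tol_s <- rt_tol_s %||% .cycle_period(run)
  scheme <- attr(run, "scheme")
  out <- list()
  for (w in scheme$window_id) {
    traces <- purrr::map(diagnostics$mz, function(mz)
      extract_xic(run, mz, tol_ppm, window = w))
    apexes <- purrr::imap(traces, function(tr, i) {
      idx <- .local_apexes(tr$intensity)
      tibble::tibble(ion = diagnostics$ion[i], trace = i,
                     rt = tr$rt_s[idx], height = tr$intensity[idx])
    })
    apexes <- dplyr::bind_rows(apexes)
    if (nrow(apexes) == 0) next
    cands <- purrr::map(seq_len(nrow(apexes)), function(i) {
      near <- apexes[abs(apexes$rt - apexes$rt[i]) <= rt_tol_s, ]
      # best apex per ion within the co-elution window
      near <- near[order(-near$height), ]
      near <- near[!duplicated(near$ion), ]
      tibble::tibble(window_id = w, apex_rt = apexes$rt[i],
                     co_detected = nrow(near),
                     summed_intensity = sum(near$height),
                     ions = list(sort(near$ion)))
    })
    cands <- dplyr::bind_rows(cands)
    cands <- cands[cands$co_detected >= min_codetected, ]
    if (nrow(cands) == 0) next
    cands <- dplyr::arrange(cands, desc(.data$co_detected),
                            desc(.data$summed_intensity))
    keep <- rep(FALSE, nrow(cands))
    for (i in seq_len(nrow(cands))) {
      if (!any(abs(cands$apex_rt[keep] - cands$apex_rt[i]) <= rt_tol_s)) {
        keep[i] <- TRUE
      }
    }
    out[[length(out) + 1]] <- cands[keep, ]
  }
  if (length(out) == 0) {
    return(tibble::tibble(window_id = integer(), apex_rt = double(),
                          co_detected = integer(),
                          summed_intensity = double(), ions = list()))
  }
  res <- dplyr::bind_rows(out)
  dplyr::arrange(res, desc(.data$co_detected), desc(.data$summed_intensity))
}

#' Stage 2: match deconvoluted precursor masses against the conjugate database
#'
#' Takes a screening candidate (window + retention time), reads the MS1
#' peaks inside that window at the nearest cycle, and tries each charge in
#' `charge_range`: a peak at m/z with charge z implies neutral mass
#' z*(m/z - proton). Conjugates whose neutral mass agrees within `tol_ppm`
#' are returned with signed ppm error, ordered by |ppm|.
#'
#' @param candidate One screening candidate (one-row tibble or list with
#'   `window_id` and `apex_rt`).
#' @param conjugates Conjugate database from [enumerate_conjugates()]
#'   (needs `neutral_mass`; extra columns are carried through).
#' @param run The `spectrum_run` providing MS1 spectra.
#' @param tol_ppm MS1 mass tolerance (ppm).
#' @param charge_range Candidate precursor charges.
#' @return A tibble of hypotheses (database columns plus `observed_mz`,
#'   `charge`, `observed_neutral`, `ppm_error`). The `status` attribute
#'   distinguishes `"no_ms1_peak"` (nothing in the window at that time)
#'   from `"no_match"` (peaks present, none matched) and `"ok"`.
#' @export
match_precursor <- function(candidate, conjugates, run, tol_ppm = 15,
                            charge_range = 2:5) {
  if (nrow(conjugates) == 0) abort("conjugate database is empty")
  scheme <- attr(run, "scheme")
  w <- candidate$window_id[[1]]
  lo <- scheme$low[scheme$window_id == w]
  hi <- scheme$high[scheme$window_id == w]
  ms1 <- run[run$ms_level == 1, ]
  i <- which.min(abs(ms1$rt_s - candidate$apex_rt[[1]]))
  mz <- ms1$mz[[i]]
  int <- ms1$intensity[[i]]
  inwin <- mz >= lo & mz < hi
  empty <- conjugates[0, setdiff(names(conjugates), "conjugate")]
  empty$observed_mz <- double()
  empty$charge <- integer()
  empty$observed_neutral <- double()
  empty$ppm_error <- double()
  if ("conjugate" %in% names(conjugates)) empty$conjugate <- list()
  if (!any(inwin)) {
    attr(empty, "status") <- "no_ms1_peak"
    return(empty)
  }
  peaks <- tibble::tibble(observed_mz = mz[inwin], intensity = int[inwin])
  grid <- tidyr::crossing(peaks, charge = as.integer(charge_range))
  grid$observed_neutral <- grid$charge *
    (grid$observed_mz - mass_constants[["proton"]])
  hits <- list()
  for (j in seq_len(nrow(conjugates))) {
    theo <- conjugates$neutral_mass[j]
    ppm <- (grid$observed_neutral - theo) / theo * 1e6
    sel <- which(abs(ppm) <= tol_ppm)
    if (length(sel) == 0) next
    # keep the best charge assignment per conjugate
    best <- sel[which.min(abs(ppm[sel]))]
    h <- conjugates[j, ]
    h$observed_mz <- grid$observed_mz[best]
    h$charge <- grid$charge[best]
    h$observed_neutral <- grid$observed_neutral[best]
    h$ppm_error <- ppm[best]
    hits[[length(hits) + 1]] <- h
  }
  if (length(hits) == 0) {
    attr(empty, "status") <- "no_match"
    return(empty)
  }
  out <- dplyr::bind_rows(hits)
  out <- dplyr::arrange(out, abs(.data$ppm_error))
  attr(out, "status") <- "ok"
  out
}

#' Stage 3: map MS/MS peaks onto theoretical conjugate fragments
#'
#' Annotates an MS2 spectrum's peaks against the conjugate's theoretical
#' fragment ions and scores the hypothesis by the fraction of theoretical
#' ions matched and by the fraction of spectrum intensity carried by
#' matched peaks. The localized site is the conjugate's link position;
#' records at or above `score_floor` are marked accepted.
#'
#' @param conjugate A [branched_conjugate()].
#' @param mz,intensity The MS2 spectrum's peak arrays.
#' @param tol_ppm Fragment tolerance (ppm).
#' @param max_charge Fragment charges emitted (1..max_charge).
#' @param score_floor Acceptance floor on the matched fraction.
#' @return One-row tibble: `protein_site`, `backbone`, `branch`,
#'   `n_theoretical`, `n_matched`, `matched_fraction`,
#'   `intensity_fraction`, `accepted`, `annotation`.
#' @export
map_fragments <- function(conjugate, mz, intensity, tol_ppm = 25,
                          max_charge = 2, score_floor = 0.3) {
  stopifnot(inherits(conjugate, "branched_conjugate"))
  if (length(mz) == 0) abort("spectrum is empty")
  theo <- fragment_conjugate(conjugate, max_charge = max_charge)
  if (nrow(theo) == 0) abort("conjugate emits no theoretical fragments")
  half <- theo$mz * tol_ppm * 1e-6
  smz <- sort(mz)
  matched <- vapply(seq_len(nrow(theo)), function(i) {
    j <- findInterval(theo$mz[i], smz)
    (j >= 1 && theo$mz[i] - smz[j] <= half[i]) ||
      (j < length(smz) && smz[j + 1] - theo$mz[i] <= half[i])
  }, logical(1))
  peak_hit <- rep(FALSE, length(mz))
  for (i in which(matched)) {
    peak_hit <- peak_hit | abs(mz - theo$mz[i]) <= half[i]
  }
  site <- conjugate$protein_site
  tibble::tibble(
    protein_site = site,
    backbone = conjugate$backbone,
    branch = conjugate$branch,
    n_theoretical = nrow(theo),
    n_matched = sum(matched),
    matched_fraction = mean(matched),
    intensity_fraction = if (sum(intensity) > 0)
      sum(intensity[peak_hit]) / sum(intensity) else 0,
    accepted = mean(matched) >= score_floor,
    annotation = sprintf("K%s conjugated with %s remnant",
                         ifelse(is.na(site), "?", site), conjugate$branch))
}

#' Three-stage DIA identification of remnant-conjugated peptides
#'
#' Runs the full procedure against a DIA run: (1) diagnostic-ion screening
#' of every isolation window, (2) precursor mass matching of screening
#' candidates against the in silico conjugate database built from the
#' supplied proteins, (3) MS/MS fragment mapping and site localization.
#'
#' @param run A `spectrum_run`.
#' @param proteins Tibble with columns `id` and `sequence` (e.g. from
#'   [read_fasta()]).
#' @param remnant Remnant sequence defining the conjugates and diagnostics.
#' @param settings A [dia_settings()] list.
#' @return A tibble of class `dia_identifications`, one accepted
#'   identification per row, with a `counts` attribute recording the
#'   funnel (peptides, conjugates, candidates, hypotheses, records).
#' @export
search_dia <- function(run, proteins, remnant = sumo1_remnant(),
                       settings = dia_settings()) {
  s <- settings
  dbs <- purrr::map(seq_len(nrow(proteins)), function(i) {
    peps <- digest(proteins$sequence[i],
                   missed_cleavages = s$missed_cleavages)
    db <- enumerate_conjugates(peps, remnant)
    if (nrow(db) > 0) db$protein <- proteins$id[i]
    db
  })
  db <- dplyr::bind_rows(dbs)
  n_peptides <- sum(purrr::map_int(proteins$sequence, function(x)
    nrow(digest(x, missed_cleavages = s$missed_cleavages))))
  diagnostics <- diagnostic_ion_set(remnant)
  cands <- screen_diagnostics(run, diagnostics, tol_ppm = s$ms2_tol_ppm,
                              min_codetected = s$min_codetected,
                              rt_tol_s = s$rt_tol_s)
  records <- list()
  n_hyp <- 0L
  if (nrow(db) > 0 && nrow(cands) > 0) {
    for (i in seq_len(nrow(cands))) {
      hyps <- match_precursor(cands[i, ], db, run,
                              tol_ppm = s$ms1_tol_ppm,
                              charge_range = s$charge_range)
      n_hyp <- n_hyp + nrow(hyps)
      if (nrow(hyps) == 0) next
      w <- cands$window_id[i]
      ms2 <- run[run$ms_level == 2 & !is.na(run$window_id) &
                   run$window_id == w, ]
      j <- which.min(abs(ms2$rt_s - cands$apex_rt[i]))
      for (h in seq_len(nrow(hyps))) {
        rec <- map_fragments(hyps$conjugate[[h]],
                             ms2$mz[[j]], ms2$intensity[[j]],
                             tol_ppm = s$ms2_tol_ppm,
                             max_charge = s$fragment_max_charge,
                             score_floor = s$score_floor)
        rec$protein <- hyps$protein[h]
        rec$window_id <- w
        rec$apex_rt <- cands$apex_rt[i]
        rec$co_detected <- cands$co_detected[i]
        rec$precursor_mz <- hyps$observed_mz[h]
        rec$precursor_charge <- hyps$charge[h]
        rec$ppm_error <- hyps$ppm_error[h]
        records[[length(records) + 1]] <- rec
      }
    }
  }
  out <- dplyr::bind_rows(records)
  if (nrow(out) > 0) {
    out <- out[out$accepted, ]
    out <- dplyr::arrange(out, desc(.data$matched_fraction))
  } else {
    out <- tibble::tibble(protein_site = integer(), backbone = character(),
                          branch = character(), n_theoretical = integer(),
                          n_matched = integer(), matched_fraction = double(),
                          intensity_fraction = double(), accepted = logical(),
                          annotation = character(), protein = character(),
                          window_id = integer(), apex_rt = double(),
                          co_detected = integer(), precursor_mz = double(),
                          precursor_charge = integer(), ppm_error = double())
  }
  attr(out, "counts") <- list(
    peptides = n_peptides, conjugates = nrow(db),
    candidates = nrow(cands), hypotheses = n_hyp, records = nrow(out))
  class(out) <- unique(c("dia_identifications", class(out)))
  out
}
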