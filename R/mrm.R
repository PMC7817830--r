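#' Build heavy-standard isotope labels for a conjugate
#'
#' Computes uniform 13C/15N mass shifts for chosen residues of either arm,
#' e.g. the canonical heavy standard for the SUMO1-conjugated peptide
#' labels the remnant Leu (position 2) and the backbone Val preceding the
#' C-terminal Arg.
#'
#' @param conjugate A [branched_conjugate()].
#' @param backbone_positions,branch_positions 1-based labeled positions.
#' @return A list with `backbone` and `branch` label tibbles, suitable for
#'   [branched_conjugate()] or [design_transitions()].
#' @examples
#' bc <- branched_conjugate("IISKIENHEGVR", 4)
#' make_heavy_labels(bc, backbone_positions = 11, branch_positions = 2)
#' @export
make_heavy_labels <- function(conjugate, backbone_positions = integer(),
                              branch_positions = integer()) {
  stopifnot(inherits(conjugate, "branched_conjugate"))
  lab <- function(seq, pos) {
    if (length(pos) == 0) return(NULL)
    res <- strsplit(seq, "")[[1]][pos]
    tibble::tibble(position = as.integer(pos), mass_shift = isotope_shift(res))
  }
  list(backbone = lab(conjugate$backbone, backbone_positions),
       branch = lab(conjugate$branch, branch_positions))
}

.transition_id <- function(peptide_id, series, index, charge, isotope) {
  sprintf("%s|%s%d^%d|%s", peptide_id, series, index, charge, isotope)
}

#' Design MRM transitions for a branched conjugate
#'
#' Selects the `n` most intense product ions — ranked by a reference MS/MS
#' spectrum when one is given, otherwise by a deterministic theoretical
#' proxy (inverse emission-order rank, the same ordering the simulator's
#' intensity model uses) — and emits each as a light/heavy transition
#' pair. An explicit `products` selection (tibble with `series`, `index`,
#' `charge`) bypasses the ranking.
#'
#' @param conjugate The (unlabeled) [branched_conjugate()].
#' @param n Number of product ions to select.
#' @param reference Optional reference spectrum (tibble/list with `mz`,
#'   `intensity`) used to rank candidates.
#' @param products Optional explicit product selection.
#' @param heavy_labels Label set from [make_heavy_labels()]; when `NULL`
#'   only light transitions are emitted.
#' @param precursor_charge Precursor charge state.
#' @param product_charges Product charges considered.
#' @param tol_ppm Match tolerance against the reference spectrum.
#' @param peptide_id Identifier used in the transition list.
#' @return A tibble of class `mrm_transitions` with columns
#'   `transition_id`, `peptide_id`, `precursor_mz`, `precursor_z`,
#'   `product_series`, `product_index`, `product_z`, `product_mz`,
#'   `isotope`.
#' @export
design_transitions <- function(conjugate, n = 4, reference = NULL,
                               products = NULL, heavy_labels = NULL,
                               precursor_charge = 3, product_charges = 1:3,
                               tol_ppm = 25, peptide_id = "peptide1") {
  stopifnot(inherits(conjugate, "branched_conjugate"))
  if (n < 1) abort("n must be >= 1")
  cand <- fragment_conjugate(conjugate, max_charge = max(product_charges))
  cand <- cand[cand$charge %in% product_charges, ]
  if (!is.null(products)) {
    sel <- dplyr::left_join(
      tibble::as_tibble(products)[c("series", "index", "charge")],
      cand, by = c("series", "index", "charge"))
    if (anyNA(sel$mz)) abort("requested product not in the candidate set")
  } else {
    if (!is.null(reference)) {
      ref_mz <- reference$mz
      ref_int <- reference$intensity
      score <- vapply(cand$mz, function(m) {
        hit <- abs(ref_mz - m) <= m * tol_ppm * 1e-6
        if (any(hit)) max(ref_int[hit]) else 0
      }, double(1))
    } else {
      score <- 1 / seq_len(nrow(cand))  # inverse emission-order rank
    }
    ord <- order(-score, cand$mz)
    if (n > nrow(cand)) {
      warn(sprintf("only %d candidate products available (requested %d)",
                   nrow(cand), n))
      n <- nrow(cand)
    }
    sel <- cand[ord[seq_len(n)], ]
  }
  build <- function(conj, isotope) {
    fr <- fragment_conjugate(conj, max_charge = max(product_charges))
    m <- dplyr::left_join(sel[c("series", "index", "charge")], fr,
                          by = c("series", "index", "charge"))
    tibble::tibble(
      transition_id = .transition_id(peptide_id, m$series, m$index,
                                     m$charge, isotope),
      peptide_id = peptide_id,
      precursor_mz = conjugate_mz(conj, precursor_charge),
      precursor_z = as.integer(precursor_charge),
      product_series = m$series, product_index = m$index,
      product_z = as.integer(m$charge), product_mz = m$mz,
      isotope = isotope)
  }
  out <- build(conjugate, "light")
  if (!is.null(heavy_labels)) {
    heavy <- branched_conjugate(conjugate$backbone, conjugate$link_pos,
                                conjugate$branch, conjugate$protein_site,
                                backbone_labels = heavy_labels$backbone,
                                branch_labels = heavy_labels$branch)
    out <- dplyr::bind_rows(out, build(heavy, "heavy"))
  }
  class(out) <- unique(c("mrm_transitions", class(out)))
  out
}

.trapz <- function(t, y) sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)

#' Integrate a chromatographic peak
#'
#' Locates the apex (the local maximum nearest `rt_hint`, or the global
#' maximum without a hint), walks boundaries outward to the first sample
#' at or below `boundary_frac` of the apex height or to a local minimum,
#' and returns the trapezoidal area between the boundaries minus a flat
#' baseline at the lower of the two boundary intensities.
#'
#' @param chromatogram Tibble/list with `time` and `intensity` vectors
#'   (>= 3 samples, strictly increasing times).
#' @param rt_hint Optional expected apex retention time (s).
#' @param boundary_frac Boundary threshold as a fraction of apex height.
#' @return One-row tibble: `area`, `apex_rt`, `left`, `right`, `flag`
#'   (`"ok"` or `"no_peak"`).
#' @export
integrate_peak <- function(chromatogram, rt_hint = NULL,
                           boundary_frac = 0.05) {
  t <- chromatogram$time
  y <- chromatogram$intensity
  if (length(t) < 3) abort("chromatogram needs at least 3 samples")
  if (any(diff(t) <= 0)) abort("times must strictly increase")
  if (all(y == 0)) {
    return(tibble::tibble(area = 0, apex_rt = NA_real_, left = NA_real_,
                          right = NA_real_, flag = "no_peak"))
  }
  apexes <- .local_apexes(y)
  if (length(apexes) == 0) apexes <- which.max(y)
  a <- if (is.null(rt_hint)) apexes[which.max(y[apexes])] else
    apexes[which.min(abs(t[apexes] - rt_hint))]
  thr <- boundary_frac * y[a]
  left <- a
  while (left > 1) {
    if (y[left - 1] <= thr) { left <- left - 1; break }
    if (y[left - 1] > y[left]) break      # local minimum at `left`
    left <- left - 1
  }
  right <- a
  n <- length(y)
  while (right < n) {
    if (y[right + 1] <= thr) { right <- right + 1; break }
    if (y[right + 1] > y[right]) break
    right <- right + 1
  }
  baseline <- min(y[left], y[right])
  area <- .trapz(t[left:right], y[left:right]) -
    baseline * (t[right] - t[left])
  tibble::tibble(area = max(area, 0), apex_rt = t[a],
                 left = t[left], right = t[right], flag = "ok")
}

#' Quantify MRM runs by light/heavy peak areas
#'
#' Transitions belonging to one peptide co-integrate over a common
#' retention-time window: the consensus apex is the median of the
#' per-trace apexes, traces deviating beyond `apex_tol_s` are flagged and
#' integrated at the consensus. Per run, areas are summed by isotopic
#' identity and the light/heavy ratio reported (flagged undefined when
#' the heavy sum is zero).
#'
#' @param chromatograms Tibble, one row per trace: `transition_id`,
#'   `run_id`, `time` (list), `intensity` (list).
#' @param transitions An [design_transitions()] table.
#' @param apex_tol_s Tolerated apex scatter among one peptide's traces.
#' @param boundary_frac Passed to [integrate_peak()].
#' @return An object of class `mrm_quant`: a list with `transitions`
#'   (per-trace areas) and `samples` (per run x peptide: summed light and
#'   heavy areas, ratio, consensus apex, flags).
#' @export
quantify_run <- function(chromatograms, transitions, apex_tol_s = 5,
                         boundary_frac = 0.05) {
  missing_tr <- setdiff(transitions$transition_id,
                        chromatograms$transition_id)
  if (length(missing_tr) > 0) {
    abort(paste("no chromatogram for transition(s):",
                paste(missing_tr, collapse = ", ")))
  }
  ch <- dplyr::left_join(chromatograms,
                         transitions[c("transition_id", "peptide_id",
                                       "isotope")],
                         by = "transition_id")
  if (anyNA(ch$peptide_id)) {
    abort("chromatogram present for a transition not in the design table")
  }
  per <- list()
  for (grp in split(seq_len(nrow(ch)),
                    paste(ch$run_id, ch$peptide_id, sep = "\r"))) {
    apex0 <- vapply(grp, function(i) {
      y <- ch$intensity[[i]]
      ch$time[[i]][which.max(y)]
    }, double(1))
    consensus <- stats::median(apex0)
    inconsistent <- abs(apex0 - consensus) > apex_tol_s
    for (k in seq_along(grp)) {
      i <- grp[k]
      pk <- integrate_peak(list(time = ch$time[[i]],
                                intensity = ch$intensity[[i]]),
                           rt_hint = consensus,
                           boundary_frac = boundary_frac)
      per[[length(per) + 1]] <- tibble::tibble(
        run_id = ch$run_id[i], peptide_id = ch$peptide_id[i],
        transition_id = ch$transition_id[i], isotope = ch$isotope[i],
        area = pk$area, apex_rt = pk$apex_rt,
        left = pk$left, right = pk$right,
        consensus_apex = consensus,
        flag = if (inconsistent[k]) "inconsistent_apex" else pk$flag)
    }
  }
  per <- dplyr::bind_rows(per)
  samples <- per |>
    dplyr::group_by(.data$run_id, .data$peptide_id) |>
    dplyr::summarise(
      light_area = sum(.data$area[.data$isotope == "light"]),
      heavy_area = sum(.data$area[.data$isotope == "heavy"]),
      consensus_apex = .data$consensus_apex[1],
      n_flagged = sum(.data$flag != "ok"),
      .groups = "drop") |>
    dplyr::mutate(
      ratio = ifelse(.data$heavy_area > 0,
                     .data$light_area / .data$heavy_area, NA_real_),
      ratio_flag = ifelse(.data$heavy_area > 0, "ok", "undefined_ratio"))
  structure(list(transitions = per, samples = samples),
            class = "mrm_quant")
}

#' @export
print.mrm_quant <- function(x, ...) {
  cat(sprintf("<mrm_quant> %d trace(s), %d run x peptide group(s)\n",
              nrow(x$transitions), nrow(x$samples)))
  print(x$samples)
  invisible(x)
}
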