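.fmt_labels <- function(label_tbl) {
  if (is.null(label_tbl) || nrow(label_tbl) == 0) return("")
  paste(sprintf("%d:+%.4f", label_tbl$position, label_tbl$mass_shift),
        collapse = ";")
}

#' Theoretical b/y fragment ions of a linear peptide
#'
#' Standard N-terminal (b) and C-terminal (y) fragment series from
#' peptide-bond cleavage: `b_i` is the residue sum of the first `i`
#' residues, `y_i` the residue sum of the last `i` residues plus one water.
#'
#' @param sequence Peptide sequence.
#' @param max_charge Emit each fragment at charges `1..max_charge`.
#' @param labels Optional isotope labels; shifts follow their residues.
#' @return A tibble with columns `series` ("b"/"y"), `index`, `charge`,
#'   `neutral_mass`, `mz`, `labels`.
#' @export
fragment_linear <- function(sequence, max_charge = 1, labels = NULL) {
  chars <- .check_sequence(sequence)
  if (max_charge < 1) abort("max_charge must be >= 1")
  lab <- as_label_tbl(labels, sequence)
  L <- length(chars)
  if (L < 2) abort("peptide too short to fragment")
  idx <- seq_len(L - 1L)
  b_neutral <- vapply(idx, function(i)
    .residue_sum(chars[1:i], lab, from = 1L), double(1))
  y_neutral <- vapply(idx, function(i)
    .residue_sum(chars[(L - i + 1):L], lab, from = L - i + 1L) +
      mass_constants[["water_mono"]], double(1))
  base <- tibble::tibble(
    series = rep(c("b", "y"), each = L - 1L),
    index = rep(idx, 2),
    neutral_mass = c(b_neutral, y_neutral))
  out <- tidyr::crossing(base, charge = seq_len(max_charge))
  out$mz <- neutral_to_mz(out$neutral_mass, out$charge)
  lab_str <- .fmt_labels(lab)
  out$labels <- if (nzchar(lab_str)) {
    purrr::map2_chr(out$series, out$index, function(s, i) {
      keep <- if (s == "b") lab$position <= i else lab$position > L - i
      .fmt_labels(lab[keep, , drop = FALSE])
    })
  } else ""
  out[c("series", "index", "charge", "neutral_mass", "mz", "labels")]
}

#' Theoretical fragment ions of a branched conjugate
#'
#' Emits four series over charges `1..max_charge`:
#' \describe{
#'   \item{backbone-b, backbone-y}{ordinary backbone fragments; any
#'     fragment spanning the link position carries the intact branch
#'     (its residue-sum mass).}
#'   \item{branch-b}{remnant N-terminal fragments; these never contain the
#'     backbone, making them substrate-independent diagnostics.}
#'   \item{branch-y'}{remnant C-terminal fragments, which retain the entire
#'     intact backbone (including its water) through the isopeptide link.}
#' }
#' Isotope-label shifts follow their residues into fragments. For every
#' `n`, `branch-y'_n` + `branch-b_(B-n)` neutral masses sum to the
#' conjugate neutral mass.
#'
#' @param conjugate A [branched_conjugate()].
#' @param series Which series to emit (default all four).
#' @param max_charge Emit each fragment at charges `1..max_charge`.
#' @return A tibble with columns `series`, `index`, `charge`,
#'   `neutral_mass`, `mz`, `carries_branch`, `carries_backbone`, `labels`.
#' @examples
#' bc <- branched_conjugate("IISKIENHEGVR", 4, protein_site = 270)
#' fr <- fragment_conjugate(bc, max_charge = 3)
#' fr[fr$series == "branch-y'" & fr$index == 2 & fr$charge == 2, ]
#' @export
fragment_conjugate <- function(conjugate,
                               series = c("backbone-b", "backbone-y",
                                          "branch-b", "branch-y'"),
                               max_charge = 1) {
  stopifnot(inherits(conjugate, "branched_conjugate"))
  series <- match.arg(series, several.ok = TRUE)
  if (max_charge < 1) abort("max_charge must be >= 1")
  bchars <- strsplit(conjugate$backbone, "")[[1]]
  rchars <- strsplit(conjugate$branch, "")[[1]]
  L <- length(bchars)
  B <- length(rchars)
  lp <- conjugate$link_pos
  blab <- conjugate$backbone_labels
  rlab <- conjugate$branch_labels
  branch_sum <- .residue_sum(rchars, rlab)
  backbone_full <- .residue_sum(bchars, blab) + mass_constants[["water_mono"]]

  piece <- function(ser, idx, neutral, c_branch, c_backbone, lab_tbl) {
    tibble::tibble(series = ser, index = idx, neutral_mass = neutral,
                   carries_branch = c_branch, carries_backbone = c_backbone,
                   labels = .fmt_labels(lab_tbl))
  }
  rows <- list()
  if ("backbone-b" %in% series && L >= 2) {
    rows <- c(rows, lapply(seq_len(L - 1L), function(i) {
      has_branch <- i >= lp
      labs <- blab[blab$position <= i, , drop = FALSE]
      if (has_branch) labs <- dplyr::bind_rows(labs, rlab)
      piece("backbone-b", i,
            .residue_sum(bchars[1:i], blab, 1L) +
              if (has_branch) branch_sum else 0,
            has_branch, TRUE, labs)
    }))
  }
  if ("backbone-y" %in% series && L >= 2) {
    rows <- c(rows, lapply(seq_len(L - 1L), function(i) {
      from <- L - i + 1L
      has_branch <- lp >= from
      labs <- blab[blab$position >= from, , drop = FALSE]
      if (has_branch) labs <- dplyr::bind_rows(labs, rlab)
      piece("backbone-y", i,
            .residue_sum(bchars[from:L], blab, from) +
              mass_constants[["water_mono"]] +
              if (has_branch) branch_sum else 0,
            has_branch, TRUE, labs)
    }))
  }
  if ("branch-b" %in% series && B >= 2) {
    rows <- c(rows, lapply(seq_len(B - 1L), function(j) {
      piece("branch-b", j, .residue_sum(rchars[1:j], rlab, 1L),
            TRUE, FALSE, rlab[rlab$position <= j, , drop = FALSE])
    }))
  }
  if ("branch-y'" %in% series && B >= 2) {
    rows <- c(rows, lapply(seq_len(B - 1L), function(j) {
      from <- B - j + 1L
      piece("branch-y'", j,
            .residue_sum(rchars[from:B], rlab, from) + backbone_full,
            TRUE, TRUE,
            dplyr::bind_rows(rlab[rlab$position >= from, , drop = FALSE],
                             blab))
    }))
  }
  base <- dplyr::bind_rows(rows)
  out <- tidyr::crossing(base, charge = seq_len(max_charge))
  out$mz <- neutral_to_mz(out$neutral_mass, out$charge)
  dplyr::arrange(
    out[c("series", "index", "charge", "neutral_mass", "mz",
          "carries_branch", "carries_backbone", "labels")],
    .data$series, .data$index, .data$charge)
}

#' Diagnostic-ion set for a SUMO remnant
#'
#' Remnant branch-b ions are the only conjugate fragments free of the
#' backbone, so their co-detection flags a remnant-conjugated peptide in a
#' DIA window regardless of substrate. The default set is the singly
#' charged branch-b1..b(B-1) series; for the canonical 19-residue SUMO1
#' remnant the doubly charged b18 is appended, giving a 19-ion panel. Any
#' explicit ion list (tibble with `series`, `index`, `charge`) can be
#' supplied instead via `ions`.
#'
#' @param remnant Remnant sequence (length >= 2).
#' @param ions Optional explicit ion selection (columns `series`, `index`,
#'   `charge`); rows are matched against the remnant's branch-b/y' table.
#' @return A tibble of fragment ions (columns as [fragment_conjugate()],
#'   without the backbone-dependent columns; `carries_backbone` is FALSE
#'   for all default ions).
#' @examples
#' nrow(diagnostic_ion_set(sumo1_remnant()))  # 19
#' nrow(diagnostic_ion_set("QTGG"))           # 3
#' @export
diagnostic_ion_set <- function(remnant = sumo1_remnant(), ions = NULL) {
  chars <- .check_sequence(remnant, "remnant")
  B <- length(chars)
  if (B < 2) abort("remnant too short: need length >= 2")
  idx <- seq_len(B - 1L)
  b_neutral <- vapply(idx, function(j) .residue_sum(chars[1:j]), double(1))
  all_b <- tibble::tibble(series = "branch-b", index = idx,
                          neutral_mass = b_neutral)
  if (is.null(ions)) {
    sel <- tibble::tibble(index = idx, charge = 1L)
    if (identical(remnant, sumo1_remnant())) {
      sel <- dplyr::bind_rows(sel, tibble::tibble(index = B - 1L, charge = 2L))
    }
    out <- dplyr::left_join(sel, all_b, by = "index")
    out$series <- "branch-b"
  } else {
    if (!all(c("series", "index", "charge") %in% names(ions))) {
      abort("ions needs columns 'series', 'index', 'charge'")
    }
    out <- dplyr::left_join(tibble::as_tibble(ions), all_b,
                            by = c("series", "index"))
    if (anyNA(out$neutral_mass)) abort("ion selection outside branch-b range")
  }
  out$mz <- neutral_to_mz(out$neutral_mass, out$charge)
  out$ion <- sprintf("%s%d^%d", sub("branch-", "", out$series),
                     out$index, out$charge)
  out[c("ion", "series", "index", "charge", "neutral_mass", "mz")]
}
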