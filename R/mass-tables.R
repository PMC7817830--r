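# Residue elemental compositions (residue = amino acid minus one water).
# Masses are derived from element masses at load time so that monoisotopic
# masses, average masses and uniform 13C/15N label shifts all come from one
# source of truth.

.element_mono <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
                   O = 15.9949146196, S = 31.97207100)
.element_avg  <- c(C = 12.0107, H = 1.00794, N = 14.0067,
                   O = 15.9994, S = 32.065)

# one row per residue: counts of C,H,N,O,S
.residue_comp <- matrix(
  c( # C  H  N  O  S
     2,  3, 1, 1, 0,  # G
     3,  5, 1, 1, 0,  # A
     3,  5, 1, 2, 0,  # S
     5,  7, 1, 1, 0,  # P
     5,  9, 1, 1, 0,  # V
     4,  7, 1, 2, 0,  # T
     3,  5, 1, 1, 1,  # C
     6, 11, 1, 1, 0,  # L
     6, 11, 1, 1, 0,  # I
     4,  6, 2, 2, 0,  # N
     4,  5, 1, 3, 0,  # D
     5,  8, 2, 2, 0,  # Q
     6, 12, 2, 1, 0,  # K
     5,  7, 1, 3, 0,  # E
     5,  9, 1, 1, 1,  # M
     6,  7, 3, 1, 0,  # H
     9,  9, 1, 1, 0,  # F
     6, 12, 4, 1, 0,  # R
     9,  9, 1, 2, 0,  # Y
    11, 10, 2, 1, 0), # W
  ncol = 5, byrow = TRUE,
  dimnames = list(c("G","A","S","P","V","T","C","L","I","N",
                    "D","Q","K","E","M","H","F","R","Y","W"),
                  c("C","H","N","O","S")))

#' Physical mass constants (Da)
#'
#' Monoisotopic proton and water masses, the average water mass, and the
#' mass shifts used throughout: carbamidomethylation of cysteine and the
#' per-atom 13C and 15N isotope increments.
#'
#' @format A named numeric vector.
#' @export
mass_constants <- c(
  proton        = 1.00727646688,
  water_mono    = unname(2 * 1.00782503207 + 15.9949146196),
  water_avg     = unname(2 * 1.00794 + 15.9994),
  carbamidomethyl = 57.02146,
  delta_13C     = 13.0033548378 - 12.0,
  delta_15N     = 15.0001088982 - 14.0030740048
)

#' Amino-acid residue mass table
#'
#' Monoisotopic and average residue masses (the mass of the residue within a
#' peptide chain, i.e. the free amino acid minus one water) for the 20
#' standard amino acids, together with the mass shift each residue acquires
#' under uniform 13C/15N stable-isotope labeling.
#'
#' @return A tibble with columns `residue`, `monoisotopic`, `average`,
#'   `n_carbon`, `n_nitrogen`, `shift_13C15N`.
#' @examples
#' residue_masses()
#' @export
residue_masses <- function() {
  comp <- .residue_comp
  tibble::tibble(
    residue      = rownames(comp),
    monoisotopic = as.numeric(comp %*% .element_mono[colnames(comp)]),
    average      = as.numeric(comp %*% .element_avg[colnames(comp)]),
    n_carbon     = unname(comp[, "C"]),
    n_nitrogen   = unname(comp[, "N"]),
    shift_13C15N = unname(comp[, "C"] * mass_constants[["delta_13C"]] +
                            comp[, "N"] * mass_constants[["delta_15N"]])
  )
}

# fast lookups used internally
.mono_mass <- local({
  tab <- as.numeric(.residue_comp %*% .element_mono[colnames(.residue_comp)])
  names(tab) <- rownames(.residue_comp)
  tab
})
.avg_mass <- local({
  tab <- as.numeric(.residue_comp %*% .element_avg[colnames(.residue_comp)])
  names(tab) <- rownames(.residue_comp)
  tab
})

.check_sequence <- function(sequence, what = "sequence") {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence)) {
    abort(sprintf("%s must be a non-empty string", what))
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), names(.mono_mass))
  if (length(bad) > 0) {
    abort(sprintf("%s contains non-amino-acid character(s): %s",
                  what, paste0("'", bad, "'", collapse = ", ")))
  }
  chars
}

#' Normalize an isotope-label specification
#'
#' Labels mark residues carrying a stable-isotope (or other) mass shift.
#' Accepted forms: `NULL` (no labels), a named numeric vector
#' (`c("2" = 7.0172)`, names are 1-based positions), or a data frame with
#' columns `position` and `mass_shift`.
#'
#' @param labels Label specification (see Details).
#' @param sequence The owning sequence, used to validate positions.
#' @return A tibble with columns `position` (integer) and `mass_shift` (Da).
#' @export
as_label_tbl <- function(labels, sequence = NULL) {
  if (is.null(labels) || (is.data.frame(labels) && nrow(labels) == 0)) {
    return(tibble::tibble(position = integer(), mass_shift = double()))
  }
  if (is.numeric(labels)) {
    if (is.null(names(labels)) || any(!nzchar(names(labels)))) {
      abort("numeric labels must be named by 1-based position")
    }
    out <- tibble::tibble(position = as.integer(names(labels)),
                          mass_shift = as.numeric(labels))
  } else if (is.data.frame(labels)) {
    if (!all(c("position", "mass_shift") %in% names(labels))) {
      abort("label data frame needs columns 'position' and 'mass_shift'")
    }
    out <- tibble::tibble(position = as.integer(labels$position),
                          mass_shift = as.numeric(labels$mass_shift))
  } else {
    abort("unsupported label specification")
  }
  if (any(out$mass_shift <= 0)) abort("label mass shifts must be > 0")
  if (anyDuplicated(out$position)) abort("at most one label per position")
  if (!is.null(sequence)) {
    n <- nchar(sequence)
    if (any(out$position < 1 | out$position > n)) {
      abort("label position outside sequence length")
    }
  }
  dplyr::arrange(out, .data$position)
}

#' Uniform 13C/15N label shift for a residue
#'
#' The monoisotopic mass increment of a residue in which every carbon is 13C
#' and every nitrogen is 15N — the labeling scheme of heavy-standard
#' peptides (e.g. Leu +7.0172 Da, Val +6.0138 Da).
#'
#' @param residue One-letter residue code(s).
#' @return Numeric vector of mass shifts (Da).
#' @examples
#' isotope_shift(c("L", "V"))
#' @export
isotope_shift <- function(residue) {
  tab <- residue_masses()
  idx <- match(residue, tab$residue)
  if (anyNA(idx)) {
    abort(sprintf("unknown residue: %s",
                  paste(residue[is.na(idx)], collapse = ", ")))
  }
  tab$shift_13C15N[idx]
}

#' Neutral mass of a linear peptide
#'
#' Sum of residue masses plus one water, plus any isotope-label shifts.
#'
#' @param sequence Peptide sequence (one-letter codes).
#' @param kind `"monoisotopic"` (default) or `"average"`.
#' @param labels Optional isotope labels (see [as_label_tbl()]).
#' @return Neutral peptide mass in Da.
#' @examples
#' peptide_mass("GG")                      # 132.0535
#' peptide_mass("IISKIENHEGVR")            # 1393.7678
#' @export
peptide_mass <- function(sequence, kind = c("monoisotopic", "average"),
                         labels = NULL) {
  kind <- match.arg(kind)
  chars <- .check_sequence(sequence)
  tab <- if (kind == "monoisotopic") .mono_mass else .avg_mass
  water <- if (kind == "monoisotopic") mass_constants[["water_mono"]] else
    mass_constants[["water_avg"]]
  lab <- as_label_tbl(labels, sequence)
  sum(tab[chars]) + water + sum(lab$mass_shift)
}

# residue-sum mass (no terminal water); internal workhorse for fragments
.residue_sum <- function(chars, label_tbl = NULL, from = 1L) {
  m <- sum(.mono_mass[chars])
  if (!is.null(label_tbl) && nrow(label_tbl) > 0) {
    keep <- label_tbl$position >= from &
      label_tbl$position < from + length(chars)
    m <- m + sum(label_tbl$mass_shift[keep])
  }
  m
}

#' m/z of an ion from its neutral mass and charge
#'
#' @param neutral_mass Neutral mass (Da).
#' @param charge Positive integer charge.
#' @return m/z in Da per unit charge.
#' @export
neutral_to_mz <- function(neutral_mass, charge) {
  if (any(charge < 1)) abort("charge must be >= 1")
  (neutral_mass + charge * mass_constants[["proton"]]) / charge
}

#' Round half-up
#'
#' Decimal rounding with ties away from zero, the convention used when
#' comparing computed m/z values with ones printed to two decimals.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
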