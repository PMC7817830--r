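#' Canonical SUMO1 tryptic remnant sequences
#'
#' The full tryptic remnant that SUMO1 leaves on a substrate lysine after
#' trypsin digestion (a 19-mer), and the short C-terminal form. Either can
#' serve as the branch of a [branched_conjugate()].
#'
#' @return A single string.
#' @export
sumo1_remnant <- function() "ELGMEEEDVIEVYQEQTGG"

#' @rdname sumo1_remnant
#' @export
qtgg_remnant <- function() "QTGG"

#' Construct a branched (isopeptide-linked) conjugate peptide
#'
#' A branched conjugate is a tryptic backbone peptide carrying a remnant
#' peptide on a lysine side chain via an isopeptide bond between the
#' remnant's C-terminal carboxyl and the lysine epsilon-amine. Forming the
#' bond releases one water, which exactly cancels the remnant's terminal
#' water: the conjugate neutral mass is the backbone peptide mass plus the
#' branch residue-sum mass.
#'
#' @param backbone Backbone peptide sequence; must carry K at `link_pos`.
#' @param link_pos 1-based position of the modified lysine in the backbone.
#' @param branch Remnant sequence (default the SUMO1 19-mer).
#' @param protein_site Residue number of the modified lysine in the parent
#'   protein (optional, used in annotations).
#' @param backbone_labels,branch_labels Isotope labels on either arm
#'   (see [as_label_tbl()]).
#' @return An object of class `branched_conjugate`.
#' @examples
#' bc <- branched_conjugate("IISKIENHEGVR", 4, protein_site = 270)
#' conjugate_mass(bc)
#' @export
branched_conjugate <- function(backbone, link_pos,
                               branch = sumo1_remnant(),
                               protein_site = NA_integer_,
                               backbone_labels = NULL,
                               branch_labels = NULL) {
  bchars <- .check_sequence(backbone, "backbone")
  .check_sequence(branch, "branch")
  link_pos <- as.integer(link_pos)
  if (link_pos < 1 || link_pos > length(bchars)) {
    abort("link_pos outside backbone length")
  }
  if (bchars[link_pos] != "K") {
    abort(sprintf("backbone residue at link_pos %d is '%s', not K",
                  link_pos, bchars[link_pos]))
  }
  structure(
    list(backbone = backbone, branch = branch, link_pos = link_pos,
         protein_site = as.integer(protein_site),
         backbone_labels = as_label_tbl(backbone_labels, backbone),
         branch_labels = as_label_tbl(branch_labels, branch)),
    class = "branched_conjugate")
}

#' @export
print.branched_conjugate <- function(x, ...) {
  pre <- substr(x$backbone, 1, x$link_pos)
  post <- substr(x$backbone, x$link_pos + 1, nchar(x$backbone))
  cat(sprintf("<branched_conjugate> %s(+%s)%s\n", pre, x$branch, post))
  cat(sprintf("  link K at backbone position %d%s\n", x$link_pos,
              if (!is.na(x$protein_site))
                sprintf(" (protein site K%d)", x$protein_site) else ""))
  cat(sprintf("  neutral monoisotopic mass %.4f Da\n", conjugate_mass(x)))
  n_lab <- nrow(x$backbone_labels) + nrow(x$branch_labels)
  if (n_lab > 0) cat(sprintf("  %d isotope label(s)\n", n_lab))
  invisible(x)
}

#' Neutral mass of a branched conjugate
#'
#' Backbone peptide mass (with its water) plus the branch residue-sum mass;
#' the isopeptide bond's water loss cancels the branch's terminal water.
#'
#' @param conjugate A [branched_conjugate()].
#' @return Neutral monoisotopic mass (Da), including any label shifts.
#' @export
conjugate_mass <- function(conjugate) {
  stopifnot(inherits(conjugate, "branched_conjugate"))
  bchars <- strsplit(conjugate$backbone, "")[[1]]
  rchars <- strsplit(conjugate$branch, "")[[1]]
  .residue_sum(bchars, conjugate$backbone_labels) +
    mass_constants[["water_mono"]] +
    .residue_sum(rchars, conjugate$branch_labels)
}

#' Precursor m/z of a branched conjugate
#'
#' @param conjugate A [branched_conjugate()].
#' @param charge Precursor charge state.
#' @return m/z (Da).
#' @export
conjugate_mz <- function(conjugate, charge) {
  neutral_to_mz(conjugate_mass(conjugate), charge)
}

#' Enumerate candidate branched conjugates from a digest
#'
#' One conjugate per (peptide, eligible lysine) pair. A conjugated lysine
#' blocks tryptic cleavage at that residue, so an eligible K is either
#' internal to its peptide (the peptide already carries the corresponding
#' missed cleavage) or the protein's C-terminal residue. Lysines at a
#' peptide C-terminus that trypsin would have cut are skipped: that peptide
#' form cannot exist with the remnant attached. Proteins with a K-to-R
#' substitution therefore yield no conjugate at the substituted site.
#'
#' @param peptides A digest tibble from [digest()] (columns `peptide`,
#'   `start`, `end`, `missed_cleavages`).
#' @param remnant Remnant sequence to attach (default SUMO1 19-mer).
#' @param protein_length Length of the parent protein; defaults to
#'   `max(peptides$end)` (exact when `peptides` covers the protein).
#' @return A tibble with columns `backbone`, `start`, `end`,
#'   `missed_cleavages`, `link_pos`, `protein_site`, `branch`,
#'   `neutral_mass`, and a `conjugate` list-column of
#'   [branched_conjugate()] objects. Zero rows when no K is eligible.
#' @export
enumerate_conjugates <- function(peptides, remnant = sumo1_remnant(),
                                 protein_length = max(peptides$end)) {
  .check_sequence(remnant, "remnant")
  rows <- vector("list", nrow(peptides))
  for (i in seq_len(nrow(peptides))) {
    pep <- peptides$peptide[i]
    chars <- strsplit(pep, "")[[1]]
    L <- length(chars)
    ks <- which(chars == "K")
    # K at the peptide C-terminus is eligible only at the protein C-terminus
    ks <- ks[ks < L | peptides$end[i] == protein_length]
    if (length(ks) == 0) next
    rows[[i]] <- tibble::tibble(
      backbone = pep,
      start = peptides$start[i],
      end = peptides$end[i],
      missed_cleavages = peptides$missed_cleavages[i],
      link_pos = ks,
      protein_site = peptides$start[i] + ks - 1L,
      branch = remnant
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(backbone = character(), start = integer(),
                          end = integer(), missed_cleavages = integer(),
                          link_pos = integer(), protein_site = integer(),
                          branch = character(), neutral_mass = double(),
                          conjugate = list()))
  }
  out$conjugate <- purrr::pmap(
    list(out$backbone, out$link_pos, out$protein_site),
    function(bb, lp, site) branched_conjugate(bb, lp, remnant, site))
  out$neutral_mass <- purrr::map_dbl(out$conjugate, conjugate_mass)
  out[c("backbone", "start", "end", "missed_cleavages", "link_pos",
        "protein_site", "branch", "neutral_mass", "conjugate")]
}
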