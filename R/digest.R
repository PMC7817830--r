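#' In silico tryptic digestion
#'
#' Cleaves a protein C-terminal to K or R except when the next residue is P,
#' and returns every peptide with up to `missed_cleavages` internal uncut
#' sites. With `missed_cleavages = 0` the peptides concatenate, in
#' coordinate order, back to the input protein.
#'
#' @param sequence Protein sequence (one-letter codes).
#' @param missed_cleavages Maximum number of missed cleavages (>= 0).
#' @param min_length Drop peptides shorter than this (default 1, keep all).
#' @return A tibble with columns `peptide`, `start`, `end` (1-based,
#'   inclusive protein coordinates) and `missed_cleavages`, ordered by
#'   `start` then `missed_cleavages`.
#' @examples
#' digest("MKRAAK")              # MK | R | AAK
#' digest("MKPR")                # no cleavage before proline
#' @export
digest <- function(sequence, missed_cleavages = 0, min_length = 1) {
  chars <- .check_sequence(sequence, "protein sequence")
  if (missed_cleavages < 0) abort("missed_cleavages must be >= 0")
  n <- length(chars)
  # cut after position i when chars[i] in K/R and chars[i+1] != P
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | chars[pmin(cut_after + 1L, n)] != "P"]
  bounds <- unique(c(0L, cut_after, n))          # segment boundaries
  starts <- head(bounds, -1) + 1L
  ends <- tail(bounds, -1)
  n_seg <- length(starts)
  out <- vector("list", n_seg)
  for (i in seq_len(n_seg)) {
    j_max <- min(n_seg, i + missed_cleavages)
    js <- i:j_max
    out[[i]] <- tibble::tibble(
      peptide = vapply(js, function(j)
        paste0(chars[starts[i]:ends[j]], collapse = ""), character(1)),
      start = starts[i],
      end = ends[js],
      missed_cleavages = js - i
    )
  }
  res <- dplyr::bind_rows(out)
  res <- res[nchar(res$peptide) >= min_length, , drop = FALSE]
  dplyr::arrange(res, .data$start, .data$missed_cleavages)
}
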