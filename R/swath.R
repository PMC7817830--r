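#' Build a SWATH isolation-window scheme
#'
#' Partitions precursor m/z space into contiguous, disjoint, half-open
#' windows `[low, high)` of fixed width, the acquisition pattern of a Q1
#' quadrupole stepped in fixed increments. The defaults (start 600, width
#' 25 amu, end 1250) give 26 windows. If the range is not divisible by the
#' width, the final window is short and flagged.
#'
#' @param start First window's lower bound (m/z).
#' @param width Window width (amu), > 0.
#' @param end Upper end of the covered range (exclusive).
#' @return A tibble of class `swath_scheme` with columns `window_id`,
#'   `low`, `high`, `short`.
#' @examples
#' nrow(swath_scheme())  # 26
#' @export
swath_scheme <- function(start = 600, width = 25, end = 1250) {
  if (width <= 0) abort("window width must be > 0")
  if (start >= end) abort("start must be < end")
  n_win <- ceiling((end - start) / width - 1e-9)
  lows <- start + width * (seq_len(n_win) - 1)
  highs <- pmin(lows + width, end)
  out <- tibble::tibble(
    window_id = seq_along(lows),
    low = lows, high = highs,
    short = (highs - lows) < width - 1e-9)
  class(out) <- c("swath_scheme", class(out))
  out
}

#' Locate the window containing an m/z value
#'
#' Windows are half-open `[low, high)`: a value on a boundary belongs to
#' the upper window. Values below the first window or at/above the last
#' window's high edge map to `NA`.
#'
#' @param scheme A [swath_scheme()].
#' @param mz Numeric vector of m/z values.
#' @return Integer vector of window ids (NA when outside the scheme).
#' @export
window_lookup <- function(scheme, mz) {
  idx <- findInterval(mz, c(scheme$low, scheme$high[nrow(scheme)]),
                      left.open = FALSE)
  idx[idx < 1 | idx > nrow(scheme)] <- NA_integer_
  as.integer(idx)
}
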