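#' Tidy a DIA identification result
#'
#' @param x A `dia_identifications` object from [search_dia()].
#' @param ... Unused.
#' @return A plain tibble, one accepted identification per row.
#' @method tidy dia_identifications
#' @export
tidy.dia_identifications <- function(x, ...) {
  out <- x
  attr(out, "counts") <- NULL
  class(out) <- setdiff(class(out), "dia_identifications")
  tibble::as_tibble(out)
}

#' Summarise the DIA search funnel
#'
#' @param x A `dia_identifications` object.
#' @param ... Unused.
#' @return A one-row tibble with the stage counts: digest peptides,
#'   candidate conjugates, screening candidates, precursor hypotheses and
#'   accepted records.
#' @method glance dia_identifications
#' @export
glance.dia_identifications <- function(x, ...) {
  cn <- attr(x, "counts")
  tibble::tibble(n_peptides = cn$peptides, n_conjugates = cn$conjugates,
                 n_candidates = cn$candidates, n_hypotheses = cn$hypotheses,
                 n_records = cn$records)
}

#' Tidy an MRM quantification
#'
#' @param x An `mrm_quant` object from [quantify_run()].
#' @param ... Unused.
#' @return The per-transition area table.
#' @method tidy mrm_quant
#' @export
tidy.mrm_quant <- function(x, ...) x$transitions

#' Summarise an MRM quantification
#'
#' @param x An `mrm_quant` object.
#' @param ... Unused.
#' @return A one-row tibble: number of runs, traces, flagged traces, and
#'   the median light/heavy ratio.
#' @method glance mrm_quant
#' @export
glance.mrm_quant <- function(x, ...) {
  tibble::tibble(
    n_runs = length(unique(x$samples$run_id)),
    n_traces = nrow(x$transitions),
    n_flagged = sum(x$transitions$flag != "ok"),
    median_ratio = stats::median(x$samples$ratio, na.rm = TRUE))
}

#' Plot an extracted ion chromatogram
#'
#' @param object An `xic_trace` from [extract_xic()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot xic_trace
#' @export
autoplot.xic_trace <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$rt_s, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "retention time (s)", y = "summed intensity",
      title = sprintf("XIC m/z %.4f (±%g ppm, %s)",
                      attr(object, "target_mz"), attr(object, "tol_ppm"),
                      if (identical(attr(object, "window"), "MS1")) "MS1"
                      else paste("window", attr(object, "window")))) +
    ggplot2::theme_minimal()
}

#' Plot MRM light/heavy ratios per run
#'
#' @param object An `mrm_quant` object.
#' @param ... Unused.
#' @return A ggplot bar chart of per-run ratios.
#' @method autoplot mrm_quant
#' @export
autoplot.mrm_quant <- function(object, ...) {
  ggplot2::ggplot(object$samples,
                  ggplot2::aes(x = .data$run_id, y = .data$ratio,
                               fill = .data$peptide_id)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "light / heavy area ratio") +
    ggplot2::theme_minimal()
}

#' Plot one spectrum of a DIA run
#'
#' @param run A `spectrum_run`.
#' @param cycle Cycle number.
#' @param window Window id, or `NULL` for the MS1 spectrum.
#' @return A ggplot stick spectrum.
#' @export
plot_spectrum <- function(run, cycle, window = NULL) {
  sub <- if (is.null(window)) {
    run[run$cycle == cycle & run$ms_level == 1, ]
  } else {
    run[run$cycle == cycle & run$ms_level == 2 &
          !is.na(run$window_id) & run$window_id == window, ]
  }
  if (nrow(sub) != 1) abort("no unique spectrum for that cycle/window")
  df <- tibble::tibble(mz = sub$mz[[1]], intensity = sub$intensity[[1]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mz, xend = .data$mz,
                                   y = 0, yend = .data$intensity)) +
    ggplot2::geom_segment() +
    ggplot2::labs(x = "m/z", y = "intensity",
                  title = sprintf("cycle %d, %s", cycle,
                                  if (is.null(window)) "MS1"
                                  else paste("window", window))) +
    ggplot2::theme_minimal()
}
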