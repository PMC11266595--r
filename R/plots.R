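# ggplot2 helpers for the main result types. All take tidy tibbles produced
# by the corresponding compute functions, so they can be re-styled freely.

#' Plot stationary probability ratios against intergenic ORFs
#'
#' @param curve output of [orf_probability_curve()] (possibly several models
#'   bound together with an extra grouping column mapped via `colour`).
#' @param colour column to map to colour (default `frame`).
#' @return A ggplot.
#' @export
plot_orf_probability_ratio <- function(curve, colour = "frame") {
  curve <- filter(curve, .data$frame != "intergenic")
  ggplot2::ggplot(curve, ggplot2::aes(.data$k, .data$log2_ratio,
                                      colour = .data[[colour]])) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "ORF length (codons)",
                  y = "log2 P(asORF) / P(igORF)") +
    ggplot2::theme_minimal()
}

#' Plot gain or loss probability ratios against intergenic ORFs
#'
#' @param curve output of [gain_loss_curve()].
#' @param what `"gain"` or `"loss"`.
#' @return A ggplot, faceted by frame with one line per selection level.
#' @export
plot_gain_loss_ratio <- function(curve, what = c("gain", "loss")) {
  what <- match.arg(what)
  ycol <- paste0("log2_", what, "_ratio")
  curve <- filter(curve, .data$frame != "intergenic")
  ggplot2::ggplot(curve, ggplot2::aes(.data$k, .data[[ycol]],
                                      linetype = .data$level)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~frame) +
    ggplot2::labs(x = "ORF length (codons)",
                  y = paste0("log2 P(", what, ", asORF) / P(", what, ", igORF)")) +
    ggplot2::theme_minimal()
}

#' Plot per-frame ORF counts from a scan
#'
#' @param x an `"asorf_scan"` object or its `summary` tibble.
#' @param with_sub use counts including sub-ORFs.
#' @return A ggplot bar chart.
#' @export
plot_frame_counts <- function(x, with_sub = FALSE) {
  s <- if (inherits(x, "asorf_scan")) x$summary else x
  ycol <- if (with_sub) "n_with_sub" else "n"
  ggplot2::ggplot(s, ggplot2::aes(.data$frame, .data[[ycol]])) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "antisense frame", y = "ORF count") +
    ggplot2::theme_minimal()
}

#' @export
#' @rdname plot_frame_counts
#' @param object an `"asorf_scan"` object.
#' @param ... passed to [plot_frame_counts()].
#' @importFrom ggplot2 autoplot
autoplot.asorf_scan <- function(object, ...) {
  plot_frame_counts(object, ...)
}
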