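#' Plot a denoised coverage profile with outliers highlighted
#'
#' One dot per window (denoised log2 ratio `p` against position in Mb),
#' flagged outlier windows in red, with a dashed line at the expectation
#' (`p = 0`), facetted by chromosome.
#'
#' @param calls A `gbs_calls` tibble (or a `gbs_profile`; then no windows are
#'   highlighted).
#' @param sample Sample id to plot (default: the first).
#' @param chrom Optional chromosome subset.
#' @return A ggplot object.
#' @export
plot_profile <- function(calls, sample = NULL, chrom = NULL) {
  df <- tibble::as_tibble(calls)
  if (!"flag" %in% names(df)) df$flag <- FALSE
  if (is.null(sample)) sample <- df$sample_id[1]
  df <- dplyr::filter(df, .data$sample_id == !!sample)
  if (!is.null(chrom)) {
    df <- dplyr::filter(df, as.character(.data$chrom) %in% !!as.character(chrom))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                   y = .data$p, colour = .data$flag)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "red")) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = "Denoised log2 coverage ratio",
                  title = sample)
}

#' @export
autoplot.gbs_calls <- function(object, ...) plot_profile(object, ...)

#' Plot per-window outlier frequency along the genome
#'
#' A heat track of the fraction of samples flagged per window, one panel per
#' chromosome, on a log-like colour scale so rare but robust loci remain
#' visible.
#'
#' @param freq A `gbs_frequency` tibble from [frequency_summary()].
#' @return A ggplot object.
#' @export
plot_frequency <- function(freq) {
  df <- tibble::as_tibble(freq)
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2e6, y = 1,
                                   fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "red",
                                 trans = "sqrt") +
    ggplot2::facet_wrap(~chrom, ncol = 1, strip.position = "left") +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank()) +
    ggplot2::labs(x = "Position (Mb)", y = NULL,
                  fill = "Outlier\nfraction")
}

#' @export
autoplot.gbs_frequency <- function(object, ...) plot_frequency(object, ...)
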