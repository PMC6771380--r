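#' Tidy a window count vector
#'
#' @param x A `gbs_counts` tibble.
#' @param ... Unused.
#' @return A plain tibble with the sample id as a column.
#' @export
tidy.gbs_counts <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x),
                sample_id = attr(x, "sample_id"), .before = 1)
}

#' One-row summary of a window count vector
#'
#' @param x A `gbs_counts` tibble.
#' @param ... Unused.
#' @return A one-row tibble: sample id, passing-read total, skipped records,
#'   window count and windows with non-zero coverage.
#' @export
glance.gbs_counts <- function(x, ...) {
  tibble::tibble(sample_id = attr(x, "sample_id"),
                 total_passing = attr(x, "total_passing"),
                 n_skipped = attr(x, "n_skipped") %||% 0L,
                 n_windows = nrow(x),
                 n_covered = sum(x$count > 0))
}

#' Tidy outlier calls
#'
#' @param x A `gbs_calls` tibble.
#' @param ... Unused.
#' @return A plain tibble of per-window calls.
#' @export
tidy.gbs_calls <- function(x, ...) tibble::as_tibble(x)

#' One-row summary of an outlier call set
#'
#' Reports the collection-level flagging statistics, including the fraction
#' of flagged windows with negative denoised values (decreased coverage).
#'
#' @param x A `gbs_calls` tibble.
#' @param ... Unused.
#' @return A one-row tibble with `n_samples`, `n_windows`, `threshold`,
#'   `prob`, `sidedness`, `n_flagged`, `frac_flagged` and
#'   `frac_flagged_negative`.
#' @export
glance.gbs_calls <- function(x, ...) {
  flagged <- x$flag
  tibble::tibble(n_samples = dplyr::n_distinct(x$sample_id),
                 n_windows = sum(!duplicated(x$window)),
                 threshold = attr(x, "threshold"),
                 prob = attr(x, "prob"),
                 sidedness = attr(x, "sidedness"),
                 n_flagged = sum(flagged),
                 frac_flagged = mean(flagged),
                 frac_flagged_negative =
                   if (any(flagged)) mean(x$p[flagged] < 0) else NA_real_)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
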