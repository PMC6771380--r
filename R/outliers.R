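#' Flag outlier windows with a robust MAD z-score
#'
#' Each sample's denoised profile is scored genome-wide with
#' \eqn{z_i = (p_i - \mathrm{median}(p)) / (1.4826 \cdot \mathrm{MAD}(p))},
#' where the median absolute deviation is scaled by 1.4826 for consistency
#' with the normal standard deviation.  A window is flagged when `|z|`
#' exceeds the standard-normal quantile of `prob` (two-sided, the default:
#' both decreased and increased coverage are of interest) or when `z` exceeds
#' it (one-sided `"upper"`).  With `prob = 0.9999` the threshold is
#' \eqn{\Phi^{-1}(0.9999) \approx 3.719}, computed at run time.
#'
#' If a sample's MAD is zero (constant profile) the score is undefined; no
#' windows are flagged and a warning is emitted.
#'
#' @param profile A `gbs_profile` tibble (or any tibble with columns
#'   `sample_id`, `chrom`, `window`, `p`).
#' @param prob Probability defining the flagging threshold (default 0.9999).
#' @param sidedness `"two_sided"` (default) or `"upper"`.
#' @return A tibble of class `gbs_calls`: the input plus columns `z` and
#'   `flag`, with attributes `threshold`, `prob` and `sidedness`.
#' @export
call_outliers <- function(profile, prob = 0.9999,
                          sidedness = c("two_sided", "upper")) {
  sidedness <- match.arg(sidedness)
  stopifnot(is.data.frame(profile), "p" %in% names(profile),
            prob > 0, prob < 1)
  if (nrow(profile) == 0) stop("empty profile", call. = FALSE)
  if (!"sample_id" %in% names(profile)) {
    profile <- dplyr::mutate(tibble::as_tibble(profile),
                             sample_id = "sample", .before = 1)
  }
  thr <- stats::qnorm(prob)

  score_one <- function(df, id) {
    med <- stats::median(df$p)
    s <- stats::mad(df$p, center = med)  # 1.4826 * median absolute deviation
    if (s == 0) {
      warning("MAD is zero for sample '", id,
              "'; no outliers can be called", call. = FALSE)
      df$z <- rep(NA_real_, nrow(df))
      df$flag <- FALSE
    } else {
      df$z <- (df$p - med) / s
      df$flag <- if (sidedness == "two_sided") abs(df$z) > thr else df$z > thr
    }
    df
  }

  out <- profile |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(~ score_one(.x, .y$sample_id)) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(names(profile)), "z", "flag")

  structure(out,
            class = c("gbs_calls", class(tibble::tibble())),
            threshold = thr, prob = prob, sidedness = sidedness)
}

# core gap-tolerant run finder on a logical vector: returns a data frame of
# (first, last, n_out) in local indices.  Flagged windows belong to the same
# stretch when separated by at most one unflagged window; two consecutive
# unflagged windows break the stretch.  Stretches start and end on flagged
# windows.
flag_runs <- function(flag, min_outliers) {
  idx <- which(flag)
  if (length(idx) == 0) {
    return(data.frame(first = integer(), last = integer(), n_out = integer()))
  }
  brk <- c(TRUE, diff(idx) > 2)  # TRUE where a new run begins
  runs <- data.frame(
    first = idx[brk],
    last = idx[c(brk[-1], TRUE)],
    n_out = tabulate(cumsum(brk)))
  runs[runs$n_out >= min_outliers, , drop = FALSE]
}

#' Assemble flagged windows into gap-tolerant outlier stretches
#'
#' Within each sample and chromosome, maximal runs of flagged windows are
#' assembled in which at most one of two consecutive windows may be
#' unflagged: single unflagged gaps are tolerated, two consecutive unflagged
#' windows end the stretch.  Stretches are trimmed to start and end on
#' flagged windows and must contain at least `min_outliers` flagged windows
#' (the default 3; 30 selects only long stretches, at least 15 Mb at 500-kb
#' windows).  Each stretch is classified as `increased` or `decreased` by the
#' sign of its mean denoised profile value.
#'
#' @param calls A `gbs_calls` tibble from [call_outliers()].
#' @param min_outliers Minimum number of flagged windows per stretch
#'   (default 3).
#' @return A tibble of class `gbs_stretches` with columns `sample_id`,
#'   `chrom`, `start_window`, `end_window` (inclusive window indices),
#'   `start`, `end` (bp, 0-based half-open), `n_outliers`, `mean_p`,
#'   `direction`.
#' @export
find_stretches <- function(calls, min_outliers = 3) {
  stopifnot(is.data.frame(calls),
            all(c("chrom", "window", "flag") %in% names(calls)),
            min_outliers >= 1)
  if (!"sample_id" %in% names(calls)) calls$sample_id <- "sample"

  out <- calls |>
    dplyr::arrange(.data$sample_id, .data$window) |>
    dplyr::group_by(.data$sample_id, .data$chrom) |>
    dplyr::group_modify(function(df, key) {
      runs <- flag_runs(df$flag, min_outliers)
      if (nrow(runs) == 0) {
        return(tibble::tibble(start_window = integer(), end_window = integer(),
                              start = numeric(), end = numeric(),
                              n_outliers = integer(), mean_p = numeric()))
      }
      tibble::tibble(
        start_window = df$window[runs$first],
        end_window = df$window[runs$last],
        start = df$start[runs$first],
        end = df$end[runs$last],
        n_outliers = runs$n_out,
        mean_p = vapply(seq_len(nrow(runs)), function(i) {
          mean(df$p[runs$first[i]:runs$last[i]])
        }, numeric(1)))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(direction = classify_direction(.data$mean_p)) |>
    dplyr::filter(!is.na(.data$start_window))

  structure(out, class = c("gbs_stretches", class(tibble::tibble())),
            min_outliers = min_outliers)
}

#' Direction of a coverage change
#'
#' A stretch whose mean denoised profile value is positive shows increased
#' coverage (duplication-like); zero or negative means decreased coverage
#' (deletion/introgression-like).  The boundary case of an exactly zero mean
#' is classified as decreased.
#'
#' @param mean_p Numeric vector of stretch-mean denoised profile values.
#' @return Character vector, `"increased"` or `"decreased"`.
#' @export
classify_direction <- function(mean_p) {
  dplyr::if_else(mean_p > 0, "increased", "decreased")
}

#' Select the longest outlier stretch
#'
#' The stretch with the most flagged windows; ties are broken by larger bp
#' span, then by chromosome order, then by lowest start coordinate.  When the
#' input holds several samples the longest stretch of each sample is
#' returned.
#'
#' @param stretches A `gbs_stretches` tibble.
#' @return A tibble with one row per sample that has at least one stretch
#'   (zero rows for an empty input).
#' @export
longest_stretch <- function(stretches) {
  stopifnot(is.data.frame(stretches))
  if (nrow(stretches) == 0) return(tibble::as_tibble(stretches))
  stretches |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::arrange(dplyr::desc(.data$n_outliers),
                   dplyr::desc(.data$end - .data$start),
                   .data$chrom, .data$start, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

#' Overlap between a detected stretch and an annotated region
#'
#' For 0-based half-open intervals, reports the fraction of the annotated
#' region covered by the detection
#' (\eqn{|A \cap B| / |B|}) and the Jaccard index
#' (\eqn{|A \cap B| / |A \cup B|}).  Intervals on different chromosomes do
#' not overlap.
#'
#' @param region A data frame (or one-row list) with columns `chrom`,
#'   `start`, `end`: the detected stretch(es).  Rows are paired with
#'   `annotated` (recycled if one of them has a single row).
#' @param annotated A data frame with columns `chrom`, `start`, `end`: the
#'   annotated region(s), e.g. a known introgression.
#' @return A tibble with columns `fraction_of_annotated` and `jaccard`.
#' @export
overlap_fraction <- function(region, annotated) {
  region <- tibble::as_tibble(region)
  annotated <- tibble::as_tibble(annotated)
  n <- max(nrow(region), nrow(annotated))
  if (nrow(region) == 1) region <- region[rep(1, n), ]
  if (nrow(annotated) == 1) annotated <- annotated[rep(1, n), ]
  stopifnot(nrow(region) == nrow(annotated))
  if (any(annotated$end <= annotated$start)) {
    stop("annotated interval has zero or negative length", call. = FALSE)
  }
  inter <- pmax(0, pmin(region$end, annotated$end) -
                  pmax(region$start, annotated$start))
  same <- as.character(region$chrom) == as.character(annotated$chrom)
  inter[!same] <- 0
  len_r <- pmax(0, region$end - region$start)
  uni <- len_r + (annotated$end - annotated$start) - inter
  uni[!same] <- len_r[!same] + (annotated$end - annotated$start)[!same]
  tibble::tibble(fraction_of_annotated = inter / (annotated$end - annotated$start),
                 jaccard = ifelse(uni > 0, inter / uni, 0))
}

#' Per-window outlier frequency across a collection
#'
#' Counts, for every window, in how many samples it was flagged, and marks
#' windows flagged in at least `threshold_fraction` of the samples as robust
#' (the inclusive boundary: a window flagged in exactly the threshold
#' fraction is robust).
#'
#' @param calls A `gbs_calls` tibble holding all samples of the collection on
#'   a common window grid.
#' @param threshold_fraction Fraction of samples in (0, 1] defining robust
#'   windows (e.g. 0.03 or 0.10).
#' @return A tibble of class `gbs_frequency` with columns `chrom`, `start`,
#'   `end`, `window`, `n_flagged`, `fraction`, `robust`, and attributes
#'   `n_samples` and `threshold_fraction`.
#' @export
frequency_summary <- function(calls, threshold_fraction = 0.03) {
  stopifnot(is.data.frame(calls),
            all(c("sample_id", "window", "flag") %in% names(calls)),
            threshold_fraction > 0, threshold_fraction <= 1)
  grids <- calls |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(g = paste(.data$window, collapse = ","), .groups = "drop")
  if (length(unique(grids$g)) > 1) {
    stop("samples are not on a common window grid", call. = FALSE)
  }
  n_samples <- nrow(grids)
  out <- calls |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c("chrom", "start", "end", "window")))) |>
    dplyr::summarise(n_flagged = sum(.data$flag), .groups = "drop") |>
    dplyr::arrange(.data$window) |>
    dplyr::mutate(fraction = .data$n_flagged / n_samples,
                  robust = .data$fraction >= threshold_fraction)
  structure(out, class = c("gbs_frequency", class(tibble::tibble())),
            n_samples = n_samples, threshold_fraction = threshold_fraction)
}
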