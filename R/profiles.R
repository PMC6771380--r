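#' Normalize window counts to counts per million read starts
#'
#' Window counts are divided by the sample's genome-wide number of
#' filter-passing reads and multiplied by 1e6, so that every sample sums to
#' one million and libraries of different depth become comparable.
#'
#' @param counts A `gbs_counts` tibble from [count_reads()].
#' @return The input with an added column `c` (normalized count per window).
#' @export
normalize_counts <- function(counts) {
  total <- attr(counts, "total_passing")
  if (is.null(total)) total <- sum(counts$count)
  if (total <= 0) {
    stop("sample '", attr(counts, "sample_id") %||% "?",
         "' has no passing reads", call. = FALSE)
  }
  counts$c <- counts$count / total * 1e6
  counts
}

#' Build a reference coverage profile
#'
#' The expected normalized count per window, against which each sample is
#' compared.  With `mode = "ancestor"` the reference is the normalized count
#' vector of a designated ancestor sample, used verbatim.  With
#' `mode = "median"` it is the per-window median over all supplied samples
#' (including, by default, any sample later compared against it), which
#' substitutes for an ancestor when pedigrees are unknown.  For an even number
#' of samples the median is the mean of the two central order statistics.
#'
#' @param samples A list of normalized `gbs_counts` tibbles (column `c`), or a
#'   long tibble with columns `sample_id`, `window`, `c`.
#' @param mode `"median"` or `"ancestor"`.
#' @param ancestor_id Sample id of the ancestor (required for
#'   `mode = "ancestor"`).
#' @return A tibble with columns `window` and `r`, with attributes `mode` and
#'   `source` (the sample ids the reference is built from).
#' @export
build_reference <- function(samples, mode = c("median", "ancestor"),
                            ancestor_id = NULL) {
  mode <- match.arg(mode)
  long <- as_long_norm(samples)
  if (nrow(long) == 0) stop("no samples supplied", call. = FALSE)
  if (mode == "ancestor") {
    if (is.null(ancestor_id)) {
      stop("ancestor_id is required for mode = 'ancestor'", call. = FALSE)
    }
    anc <- dplyr::filter(long, .data$sample_id == ancestor_id)
    if (nrow(anc) == 0) {
      stop("unknown ancestor_id '", ancestor_id, "'", call. = FALSE)
    }
    ref <- dplyr::arrange(dplyr::select(anc, "window", r = "c"), .data$window)
    src <- ancestor_id
  } else {
    ref <- long |>
      dplyr::group_by(.data$window) |>
      dplyr::summarise(r = stats::median(.data$c), .groups = "drop") |>
      dplyr::arrange(.data$window)
    src <- unique(long$sample_id)
  }
  structure(ref, mode = mode, source = src)
}

# coerce a list of normalized gbs_counts, or an already-long tibble,
# to (sample_id, window, c)
as_long_norm <- function(samples) {
  if (is.data.frame(samples)) {
    stopifnot(all(c("sample_id", "window", "c") %in% names(samples)))
    return(tibble::as_tibble(samples)[c("sample_id", "window", "c")])
  }
  purrr::map_dfr(samples, function(s) {
    stopifnot("c" %in% names(s))
    tibble::tibble(sample_id = attr(s, "sample_id") %||% "sample",
                   window = s$window, c = s$c)
  })
}

#' Coverage log2 ratio against a reference profile
#'
#' For every window computes \eqn{d_i = \log_2((c_i+\varepsilon)/(r_i+\varepsilon))},
#' where \eqn{\varepsilon = 10^6/N} is the expected number of reads per window.
#' The pseudocount keeps the ratio finite in empty windows and dampens noise
#' where coverage is sparse.
#'
#' @param sample A normalized `gbs_counts` tibble (column `c`).
#' @param reference A reference tibble from [build_reference()] (columns
#'   `window`, `r`), or a numeric vector of per-window reference values.
#' @param epsilon Pseudocount; defaults to the grid's \eqn{10^6/N} carried on
#'   the sample.
#' @return The sample tibble with added columns `r` and `d`.
#' @export
log_ratio <- function(sample, reference, epsilon = attr(sample, "epsilon")) {
  if (is.null(epsilon) || !is.finite(epsilon) || epsilon <= 0) {
    stop("epsilon must be a positive number", call. = FALSE)
  }
  r <- if (is.data.frame(reference)) {
    if (nrow(reference) != nrow(sample)) {
      stop("reference length (", nrow(reference),
           ") does not match sample length (", nrow(sample), ")",
           call. = FALSE)
    }
    reference$r[match(sample$window, reference$window)]
  } else {
    if (length(reference) != nrow(sample)) {
      stop("reference length (", length(reference),
           ") does not match sample length (", nrow(sample), ")",
           call. = FALSE)
    }
    as.numeric(reference)
  }
  sample$r <- r
  sample$d <- log2((sample$c + epsilon) / (r + epsilon))
  sample
}

#' Denoise a log2-ratio profile with a per-chromosome rolling mean
#'
#' Applies a centered rolling average of width `k` to `d` separately within
#' each chromosome (smoothing never mixes chromosomes).  At chromosome ends
#' the window is truncated to the available values, so the output has the
#' same length as the input.
#'
#' @param profile A tibble with columns `chrom` and `d` (and optionally
#'   `sample_id` when holding several samples).
#' @param k Odd rolling-window width in windows (default 5).
#' @return The input with an added column `p`, the denoised profile.
#' @export
denoise <- function(profile, k = 5) {
  if (k < 1 || k %% 2 == 0) {
    stop("k must be an odd positive integer", call. = FALSE)
  }
  stopifnot(all(c("chrom", "d") %in% names(profile)))
  grp <- intersect(c("sample_id", "chrom"), names(profile))
  profile |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(p = zoo::rollapply(.data$d, width = k, FUN = mean,
                                     partial = TRUE, align = "center")) |>
    dplyr::ungroup()
}

#' Compute denoised coverage profiles for a sample collection
#'
#' End-to-end profile construction: normalizes every sample to counts per
#' million, builds the reference (per-window median across the collection, or
#' a designated ancestor), computes the pseudocount-stabilised log2 ratio
#' `d`, and denoises it into `p` with a per-chromosome rolling mean.
#'
#' @param samples A list of `gbs_counts` tibbles on a common window grid.
#' @param windows The `gbs_windows` grid the counts were made on.
#' @param reference `"median"` or `"ancestor"`.
#' @param ancestor_id Ancestor sample id when `reference = "ancestor"`.
#' @param k Rolling-mean width (odd; default 5).
#' @param leave_one_out With the median reference, exclude each sample from
#'   its own reference (default `FALSE`: the median is taken over all
#'   samples).
#' @return A long tibble of class `gbs_profile` with columns `sample_id`,
#'   `chrom`, `start`, `end`, `window`, `count`, `c`, `r`, `d`, `p`.
#' @export
coverage_profiles <- function(samples, windows,
                              reference = c("median", "ancestor"),
                              ancestor_id = NULL, k = 5,
                              leave_one_out = FALSE) {
  reference <- match.arg(reference)
  stopifnot(inherits(windows, "gbs_windows"), length(samples) >= 1)
  eps <- window_epsilon(windows)
  norm <- lapply(samples, normalize_counts)
  ids <- vapply(norm, function(s) attr(s, "sample_id") %||% "sample",
                character(1))

  per_sample <- function(s, ref) {
    prof <- denoise(log_ratio(s, ref, epsilon = eps), k = k)
    dplyr::mutate(tibble::as_tibble(prof),
                  sample_id = attr(s, "sample_id") %||% "sample", .before = 1)
  }

  if (reference == "median" && isTRUE(leave_one_out) && length(norm) > 1) {
    out <- purrr::imap_dfr(norm, function(s, i) {
      ref <- build_reference(norm[-i], mode = "median")
      per_sample(s, ref)
    })
    ref_attr <- list(mode = "median_loo", source = ids)
  } else {
    ref <- build_reference(norm, mode = reference, ancestor_id = ancestor_id)
    out <- purrr::map_dfr(norm, per_sample, ref = ref)
    ref_attr <- list(mode = attr(ref, "mode"), source = attr(ref, "source"))
  }

  structure(out,
            class = c("gbs_profile", class(tibble::tibble())),
            epsilon = eps,
            k = k,
            reference_mode = ref_attr$mode,
            reference_source = ref_attr$source,
            window_size = attr(windows, "window_size"))
}
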