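#' Tabulate GBS read-start loci in a region
#'
#' GBS reads begin at restriction-enzyme cut sites, so distinct alignment
#' start positions mark distinct GBS fragment loci.  Within `region`, every
#' reference position that is the leftmost aligned start of at least one
#' filter-passing read in any sample (strand-ignored) defines a locus; loci
#' whose read count summed over all supplied samples is below `min_combined`
#' are removed as unreliably covered.
#'
#' @param samples A named list of per-sample alignment record data frames
#'   (columns `chrom`, `pos` 0-based, `flag`, `mapq`, `cigar`), or a single
#'   long data frame with a `sample_id` column.
#' @param region A list or one-row data frame with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param min_combined Minimum combined read count to retain a locus
#'   (default 10; "at least" is inclusive, so a combined count of exactly
#'   `min_combined` is retained).
#' @param policy A [read_filter_policy()] applied to the reads (the same
#'   filter as window counting, by default).
#' @return A tibble of class `gbs_locus_table` with columns `pos`,
#'   `sample_id`, `count` (complete over all retained locus x sample pairs,
#'   zeros included), sorted by position; attributes `region`, `min_combined`
#'   and `samples` (the sample ids, in input order).
#' @export
build_locus_table <- function(samples, region, min_combined = 10,
                              policy = read_filter_policy()) {
  region <- as.list(tibble::as_tibble(region)[1, ])
  stopifnot(all(c("chrom", "start", "end") %in% names(region)))
  if (is.data.frame(samples)) {
    stopifnot("sample_id" %in% names(samples))
    long <- tibble::as_tibble(samples)
    ids <- unique(long$sample_id)
  } else {
    if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
      stop("samples list must be named by sample id", call. = FALSE)
    }
    ids <- names(samples)
    long <- purrr::imap_dfr(samples, function(df, id) {
      dplyr::mutate(tibble::as_tibble(df), sample_id = id, .before = 1)
    })
  }

  pass <- long[passes_filter(long, policy), , drop = FALSE]
  hits <- pass |>
    dplyr::filter(as.character(.data$chrom) == as.character(region$chrom),
                  .data$pos >= region$start, .data$pos < region$end) |>
    dplyr::count(.data$pos, .data$sample_id, name = "count")

  retained <- hits |>
    dplyr::group_by(.data$pos) |>
    dplyr::summarise(combined = sum(.data$count), .groups = "drop") |>
    dplyr::filter(.data$combined >= min_combined)

  out <- hits |>
    dplyr::filter(.data$pos %in% retained$pos) |>
    tidyr::complete(pos = retained$pos,
                    sample_id = ids,
                    fill = list(count = 0L)) |>
    dplyr::mutate(sample_id = factor(.data$sample_id, levels = ids)) |>
    dplyr::arrange(.data$pos, .data$sample_id) |>
    dplyr::mutate(sample_id = as.character(.data$sample_id))

  structure(out, class = c("gbs_locus_table", class(tibble::tibble())),
            region = region, min_combined = min_combined, samples = ids)
}

#' Presence/absence partition of loci across samples
#'
#' A sample "has" a locus when at least one of its reads starts there.  Every
#' locus is assigned to exactly one membership pattern (the subset of samples
#' having it), and loci are counted per pattern — the partition underlying a
#' Venn diagram.  Patterns sum to the retained locus total; loci covered by
#' no listed sample are counted under the empty pattern.
#'
#' @param table A `gbs_locus_table` from [build_locus_table()].
#' @param sample_ids Samples to partition over, in display order (default:
#'   all samples of the table).
#' @return A tibble with one logical column per sample, a `pattern` label
#'   (sample ids joined by `&`, `"none"` for the empty pattern) and
#'   `n_loci`; all `2^k` patterns are listed, zeros included.
#' @export
presence_partition <- function(table, sample_ids = attr(table, "samples")) {
  stopifnot(inherits(table, "gbs_locus_table"))
  unknown <- setdiff(sample_ids, attr(table, "samples"))
  if (length(unknown) > 0) {
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  wide <- table |>
    dplyr::filter(.data$sample_id %in% sample_ids) |>
    dplyr::mutate(present = .data$count >= 1L) |>
    dplyr::select("pos", "sample_id", "present") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "present",
                       values_fill = FALSE)

  grid <- rev(expand.grid(rev(stats::setNames(
    rep(list(c(TRUE, FALSE)), length(sample_ids)), sample_ids))))
  grid <- tibble::as_tibble(grid)

  if (nrow(wide) == 0) {
    counts <- rep(0L, nrow(grid))
  } else {
    key_obs <- apply(as.matrix(wide[sample_ids]), 1, paste, collapse = "")
    key_grid <- apply(as.matrix(grid[sample_ids]), 1, paste, collapse = "")
    counts <- as.integer(table(factor(key_obs, levels = key_grid)))
  }
  grid$pattern <- apply(grid[sample_ids], 1, function(row) {
    if (!any(row)) "none" else paste(sample_ids[row], collapse = "&")
  })
  grid$n_loci <- counts
  grid
}
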