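#' Count filtered read starts per genomic window
#'
#' Each alignment record passing the [read filter][passes_filter()] increments
#' the window containing its leftmost aligned reference position; failing
#' records are ignored.  The total number of passing reads is recorded and, by
#' construction, equals the sum of the window counts.
#'
#' @param records A data frame of alignment records with columns `chrom`,
#'   `pos` (0-based leftmost aligned position), `flag`, `mapq`, `cigar`.
#' @param windows A [gbs_windows][build_windows()] grid.
#' @param policy A [read_filter_policy()].
#' @param sample_id Sample identifier stored on the result.
#' @param on_unknown What to do with passing records on chromosomes absent
#'   from the grid (or beyond the chromosome end): `"skip"` drops them and
#'   keeps a tally, `"error"` aborts.
#'
#' @return A tibble of class `gbs_counts` with the window grid columns plus
#'   `count`, and attributes `sample_id`, `total_passing` (passing reads
#'   counted into windows) and `n_skipped`.
#' @export
count_reads <- function(records, windows, policy = read_filter_policy(),
                        sample_id = "sample", on_unknown = c("skip", "error")) {
  on_unknown <- match.arg(on_unknown)
  stopifnot(inherits(windows, "gbs_windows"),
            is.data.frame(records),
            all(c("chrom", "pos") %in% names(records)))

  keep <- passes_filter(records, policy)
  idx <- window_index(windows, records$chrom[keep], records$pos[keep])
  unknown <- is.na(idx)
  if (any(unknown) && on_unknown == "error") {
    stop(sum(unknown), " passing record(s) on chromosomes/positions outside ",
         "the window grid", call. = FALSE)
  }
  idx <- idx[!unknown]

  counts <- tabulate(idx, nbins = nrow(windows))
  out <- tibble::as_tibble(windows)
  out$count <- as.integer(counts)
  structure(out,
            class = c("gbs_counts", class(tibble::tibble())),
            sample_id = sample_id,
            total_passing = length(idx),
            n_skipped = sum(unknown),
            window_size = attr(windows, "window_size"),
            epsilon = attr(windows, "epsilon"))
}

#' Count filtered read starts per window from a BAM file
#'
#' Convenience wrapper around [count_reads()] that streams the needed fields
#' (flag, chromosome, position, MAPQ, CIGAR) from a BAM file via `Rsamtools`.
#'
#' @inheritParams count_reads
#' @param bam Path to a BAM file (an index is not required).
#' @param sample_id Sample identifier; defaults to the BAM file name without
#'   extension.
#' @return A `gbs_counts` tibble; see [count_reads()].
#' @export
count_reads_bam <- function(bam, windows, policy = read_filter_policy(),
                            sample_id = NULL, on_unknown = c("skip", "error")) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("count_reads_bam() requires the Rsamtools package", call. = FALSE)
  }
  if (is.null(sample_id)) {
    sample_id <- sub("\\.bam$", "", basename(bam))
  }
  param <- Rsamtools::ScanBamParam(
    what = c("flag", "rname", "pos", "mapq", "cigar"))
  raw <- Rsamtools::scanBam(bam, param = param)[[1]]
  records <- tibble::tibble(
    flag = raw$flag,
    chrom = as.character(raw$rname),
    pos = raw$pos - 1L,  # BAM reports 1-based leftmost positions
    mapq = raw$mapq,
    cigar = raw$cigar)
  # unmapped records have NA position; they fail the filter, but give them a
  # placeholder so window lookup stays well-defined
  records$pos[is.na(records$pos)] <- 0L
  records$chrom[is.na(records$chrom)] <- levels(windows$chrom)[1]
  count_reads(records, windows, policy, sample_id = sample_id,
              on_unknown = on_unknown)
}

#' Sample totals of a counts collection
#'
#' @param samples A list of `gbs_counts` tibbles.
#' @return A tibble with `sample_id`, `total_passing` and `n_skipped`.
#' @export
sample_totals <- function(samples) {
  purrr::map_dfr(samples, function(s) {
    tibble::tibble(sample_id = attr(s, "sample_id"),
                   total_passing = attr(s, "total_passing"),
                   n_skipped = attr(s, "n_skipped") %||% 0L)
  })
}

#' Discard samples with too few passing reads
#'
#' Samples whose genome-wide number of filter-passing reads is strictly below
#' `min_reads` are moved to the discarded set; the input order is preserved in
#' both sets.  Low-coverage libraries produce noisy profiles whose apparent
#' outliers reflect sampling error rather than chromosomal modifications.
#'
#' @param samples A list of `gbs_counts` tibbles.
#' @param min_reads Minimum passing-read total to keep a sample
#'   (default 100,000; "fewer than" is strict, so a sample with exactly
#'   `min_reads` reads is kept).
#' @return A list with elements `kept` and `discarded`, each a (possibly
#'   empty) list of `gbs_counts`.
#' @export
qc_samples <- function(samples, min_reads = 100000) {
  totals <- vapply(samples, function(s) as.numeric(attr(s, "total_passing")),
                   numeric(1))
  list(kept = samples[totals >= min_reads],
       discarded = samples[totals < min_reads])
}

#' Bind a counts collection into one long tibble
#'
#' @param samples A list of `gbs_counts` tibbles.
#' @return A long tibble with columns `sample_id`, `chrom`, `start`, `end`,
#'   `window`, `count`.
#' @export
bind_counts <- function(samples) {
  purrr::map_dfr(samples, function(s) {
    dplyr::mutate(tibble::as_tibble(s),
                  sample_id = attr(s, "sample_id"), .before = 1)
  })
}
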