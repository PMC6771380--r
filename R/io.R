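#' Write / read a per-sample window count table
#'
#' Plain TSV with columns `chrom`, `start`, `end`, `count` (0-based half-open
#' coordinates), preceded by comment lines recording the sample id and the
#' genome-wide passing-read total, so that reading the file back reproduces
#' the `gbs_counts` object exactly.
#'
#' @param counts A `gbs_counts` tibble.
#' @param path Output file.
#' @return `path`, invisibly (`write_counts_tsv`); a `gbs_counts` tibble
#'   (`read_counts_tsv`).
#' @export
write_counts_tsv <- function(counts, path) {
  stopifnot(inherits(counts, "gbs_counts"))
  hdr <- c(paste0("# sample_id=", attr(counts, "sample_id")),
           paste0("# total_passing=", attr(counts, "total_passing")))
  writeLines(hdr, path)
  readr::write_tsv(
    dplyr::mutate(tibble::as_tibble(counts)[c("chrom", "start", "end", "count")],
                  chrom = as.character(.data$chrom)),
    path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  head2 <- readLines(path, n = 2)
  meta <- sub("^# ", "", head2[startsWith(head2, "# ")])
  meta <- stats::setNames(sub("^[^=]*=", "", meta), sub("=.*$", "", meta))
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = "ciii")
  lens <- tapply(tab$end, tab$chrom, max)
  lens <- lens[unique(tab$chrom)]  # keep file order
  windows <- build_windows(stats::setNames(as.numeric(lens), names(lens)),
                           window_size = max(tab$end - tab$start))
  if (nrow(windows) != nrow(tab) || any(windows$start != tab$start)) {
    stop("count table does not form a regular window grid: ", path,
         call. = FALSE)
  }
  out <- tibble::as_tibble(windows)
  out$count <- as.integer(tab$count)
  structure(out,
            class = c("gbs_counts", class(tibble::tibble())),
            sample_id = unname(meta["sample_id"]) %||% basename(path),
            total_passing = as.integer(meta["total_passing"]) %||% sum(tab$count),
            n_skipped = 0L,
            window_size = attr(windows, "window_size"),
            epsilon = attr(windows, "epsilon"))
}

#' Write a coverage profile table
#'
#' One row per sample and window with the normalized count `c`, reference
#' `r`, log2 ratio `d` and denoised value `p`.
#'
#' @param profile A `gbs_profile` tibble.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  cols <- intersect(c("sample_id", "chrom", "start", "end", "c", "r", "d", "p"),
                    names(profile))
  readr::write_tsv(dplyr::mutate(tibble::as_tibble(profile)[cols],
                                 chrom = as.character(.data$chrom)), path)
  invisible(path)
}

#' Write outlier stretches as BED6
#'
#' 0-based half-open, tab-separated, no header: `chrom`, `start`, `end`,
#' `name` (`sample:direction`), `score` (number of flagged windows),
#' `strand` (`.`).  An empty stretch set produces an empty file.
#'
#' @param stretches A `gbs_stretches` tibble.
#' @param path Output BED file.
#' @return `path`, invisibly.
#' @export
write_stretches_bed <- function(stretches, path) {
  if (nrow(stretches) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.",
                   as.character(stretches$chrom),
                   as.integer(stretches$start), as.integer(stretches$end),
                   paste0(stretches$sample_id, ":", stretches$direction),
                   as.integer(stretches$n_outliers))
  writeLines(lines, path)
  invisible(path)
}

#' Render a genomic region in Mb for human-readable reports
#'
#' @param chrom,start,end Region (bp, 0-based half-open).
#' @return Strings like `"chr4H:631.5-647M"`.
#' @export
format_region_mb <- function(chrom, start, end) {
  sprintf("%s:%s-%sM", as.character(chrom),
          format(start / 1e6, trim = TRUE, scientific = FALSE, digits = 10),
          format(end / 1e6, trim = TRUE, scientific = FALSE, digits = 10))
}
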