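#' Build a fixed non-overlapping window grid over a genome
#'
#' Divides every chromosome into consecutive, non-overlapping windows of
#' `window_size` bp (the last window of a chromosome may be shorter), the
#' coordinate system in which read starts are counted and coverage profiles
#' are computed.  All coordinates are 0-based half-open, matching BAM/BED
#' conventions.
#'
#' Alongside the grid itself the object carries the pseudocount
#' \eqn{\varepsilon = 10^6 / N}, the expected number of reads per window for a
#' library normalised to one million read starts over the \eqn{N} windows of
#' the genome.  It stabilises the coverage log2 ratio in sparsely covered
#' windows.
#'
#' @param chrom_lengths Chromosome lengths in bp: a named numeric vector, or a
#'   data frame with columns `chrom` and `length`.
#' @param window_size Window width in bp (default 500,000).
#'
#' @return A tibble of class `gbs_windows` with columns `chrom` (factor,
#'   keeping chromosome order), `start`, `end` (0-based half-open bp) and
#'   `window` (1-based index over the whole genome), and attributes
#'   `window_size`, `n_windows`, `epsilon` and `chrom_lengths`.
#'
#' @examples
#' gw <- build_windows(c(chr1 = 1.2e6), window_size = 5e5)
#' attr(gw, "epsilon")  # 1e6 / 3
#' @export
build_windows <- function(chrom_lengths, window_size = 500000) {
  if (is.data.frame(chrom_lengths)) {
    stopifnot(all(c("chrom", "length") %in% names(chrom_lengths)))
    lens <- stats::setNames(as.numeric(chrom_lengths$length),
                            as.character(chrom_lengths$chrom))
  } else {
    lens <- chrom_lengths
  }
  if (length(lens) == 0) {
    stop("chromosome list is empty", call. = FALSE)
  }
  if (is.null(names(lens)) || any(!nzchar(names(lens)))) {
    stop("chromosome lengths must be named", call. = FALSE)
  }
  if (anyDuplicated(names(lens))) {
    stop("duplicated chromosome name: ",
         names(lens)[duplicated(names(lens))][1], call. = FALSE)
  }
  bad <- names(lens)[!is.finite(lens) | lens <= 0]
  if (length(bad) > 0) {
    stop("non-positive length for chromosome ", bad[1], call. = FALSE)
  }
  if (!is.numeric(window_size) || length(window_size) != 1 || window_size <= 0) {
    stop("window_size must be a single positive number", call. = FALSE)
  }

  grid <- purrr::map2_dfr(names(lens), unname(lens), function(chrom, len) {
    starts <- seq(0, len - 1, by = window_size)
    tibble::tibble(chrom = chrom,
                   start = starts,
                   end = pmin(starts + window_size, len))
  })
  grid$chrom <- factor(grid$chrom, levels = names(lens))
  grid$window <- seq_len(nrow(grid))

  structure(grid,
            class = c("gbs_windows", class(grid)),
            window_size = window_size,
            n_windows = nrow(grid),
            epsilon = 1e6 / nrow(grid),
            chrom_lengths = lens)
}

#' Pseudocount of a window grid
#'
#' @param windows A `gbs_windows` grid (or any object carrying one, e.g. a
#'   `gbs_counts` tibble).
#' @return The pseudocount \eqn{\varepsilon = 10^6/N} where `N` is the total
#'   number of windows.
#' @export
window_epsilon <- function(windows) {
  eps <- attr(windows, "epsilon")
  if (is.null(eps)) stop("no window grid attached to this object", call. = FALSE)
  eps
}

#' Read chromosome lengths from a FASTA index (.fai)
#'
#' A FASTA index is tab-separated with the sequence name in column 1 and its
#' length in column 2; only those two columns are used.
#'
#' @param path Path to a `.fai` (or any name/length TSV) file.
#' @return A named numeric vector of chromosome lengths.
#' @export
read_fai <- function(path) {
  fai <- utils::read.table(path, sep = "\t", header = FALSE, fill = TRUE,
                           stringsAsFactors = FALSE)
  if (ncol(fai) < 2) stop("not a FASTA index: ", path, call. = FALSE)
  stats::setNames(as.numeric(fai[[2]]), as.character(fai[[1]]))
}

#' Locate windows containing genomic positions
#'
#' @param windows A `gbs_windows` grid.
#' @param chrom Chromosome names (recycled against `pos`).
#' @param pos 0-based positions.
#' @return Integer window indices (`NA` for positions outside the grid).
#' @keywords internal
window_index <- function(windows, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(pos, n)
  lens <- attr(windows, "chrom_lengths")
  w <- attr(windows, "window_size")
  first <- match(levels(windows$chrom), windows$chrom)  # first window per chrom
  ci <- match(chrom, levels(windows$chrom))
  idx <- first[ci] + floor(pos / w)
  len_ok <- !is.na(ci) & pos >= 0 & pos < lens[ci]
  idx[!len_ok] <- NA_integer_
  as.integer(idx)
}
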