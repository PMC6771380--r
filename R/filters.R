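#' Read filter policy for counting GBS alignments
#'
#' Only high-quality primary alignments are counted: a record passes when it
#' is mapped, is neither a secondary nor a supplementary alignment, has
#' mapping quality of at least `min_mapq` (PHRED), and retains at least
#' `min_aligned_bases` non-clipped query bases (read length minus soft- and
#' hard-clipped bases), i.e. is not overclipped.
#'
#' @param min_mapq Minimum mapping quality, PHRED scale (default 20).
#' @param min_aligned_bases Minimum non-clipped query bases (default 30).
#' @param count_both_mates For paired-end data, whether both mates are counted
#'   independently when each passes (default `TRUE`); when `FALSE` only
#'   first-in-pair records are eligible.
#' @return A list of class `read_filter_policy`.
#' @export
read_filter_policy <- function(min_mapq = 20, min_aligned_bases = 30,
                               count_both_mates = TRUE) {
  stopifnot(min_mapq >= 0, min_aligned_bases >= 0)
  structure(list(min_mapq = min_mapq,
                 min_aligned_bases = min_aligned_bases,
                 count_both_mates = count_both_mates),
            class = "read_filter_policy")
}

# SAM flag bits
FLAG_PAIRED <- 0x1L
FLAG_UNMAPPED <- 0x4L
FLAG_SECOND_IN_PAIR <- 0x80L
FLAG_SECONDARY <- 0x100L
FLAG_SUPPLEMENTARY <- 0x800L

#' Number of non-clipped query bases implied by a CIGAR string
#'
#' Sums the lengths of the query-consuming, non-clipped operations
#' (M, I, =, X).  Hard clips never consume query bases and soft clips are
#' excluded, so this is the read length minus all clipped bases.
#'
#' Invalid CIGAR strings (including the unavailable marker `"*"`) yield `NA`
#' with a warning; callers treat such records as failing the filter.
#'
#' @param cigar Character vector of CIGAR strings.
#' @return Integer vector of non-clipped query lengths (`NA` if unparseable).
#' @export
cigar_aligned_bases <- function(cigar) {
  cigar <- as.character(cigar)
  ok <- !is.na(cigar) & grepl("^([0-9]+[MIDNSHP=X])+$", cigar)
  if (any(!ok)) {
    warning(sum(!ok), " record(s) with unparseable CIGAR treated as failing",
            call. = FALSE)
  }
  out <- rep(NA_integer_, length(cigar))
  if (any(ok)) {
    if (requireNamespace("GenomicAlignments", quietly = TRUE)) {
      out[ok] <- GenomicAlignments::cigarWidthAlongQuerySpace(
        cigar[ok], after.soft.clipping = TRUE)
    } else {
      # query-consuming ops minus soft clips, via op-wise extraction
      out[ok] <- vapply(cigar[ok], function(cg) {
        lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
        ops <- regmatches(cg, gregexpr("[MIDNSHP=X]", cg))[[1]]
        sum(lens[ops %in% c("M", "I", "=", "X")])
      }, integer(1), USE.NAMES = FALSE)
    }
  }
  out
}

#' Apply the read filter to alignment records
#'
#' @param records A data frame of alignment records with columns `flag`
#'   (integer SAM flag), `mapq` and `cigar`.  Missing MAPQ (255 in BAM or
#'   `NA`) fails the quality test.
#' @param policy A [read_filter_policy()].
#' @return Logical vector, `TRUE` for records that pass.
#' @examples
#' recs <- tibble::tibble(flag = c(0L, 256L), mapq = c(60L, 60L),
#'                        cigar = c("100M", "100M"))
#' passes_filter(recs)
#' @export
passes_filter <- function(records, policy = read_filter_policy()) {
  stopifnot(is.data.frame(records),
            all(c("flag", "mapq", "cigar") %in% names(records)))
  flag <- as.integer(records$flag)
  mapped <- bitwAnd(flag, FLAG_UNMAPPED) == 0L
  primary <- bitwAnd(flag, FLAG_SECONDARY) == 0L &
    bitwAnd(flag, FLAG_SUPPLEMENTARY) == 0L
  mate_ok <- if (isTRUE(policy$count_both_mates)) {
    rep(TRUE, length(flag))
  } else {
    bitwAnd(flag, FLAG_PAIRED) == 0L | bitwAnd(flag, FLAG_SECOND_IN_PAIR) == 0L
  }
  mapq <- suppressWarnings(as.integer(records$mapq))
  mapq_ok <- !is.na(mapq) & mapq != 255L & mapq >= policy$min_mapq
  aligned <- cigar_aligned_bases(records$cigar)
  clip_ok <- !is.na(aligned) & aligned >= policy$min_aligned_bases
  mapped & primary & mate_ok & mapq_ok & clip_ok
}
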