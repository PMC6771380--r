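# Brute-force oracle for gap-tolerant outlier stretches.
#
# Enumerates every candidate interval [i, j] of a boolean flag vector and
# keeps those satisfying the literal rule: both ends flagged, at least
# `min_outliers` flagged windows inside, and never two consecutive unflagged
# windows inside.  The reported stretches are the maximal valid intervals.
# Prefix sums make the per-interval checks O(1) but the enumeration stays
# exhaustive and independent of the run-merging algorithm under test.
oracle_stretches <- function(flag, min_outliers) {
  n <- length(flag)
  cf <- c(0L, cumsum(flag))                      # flagged in [1, t] = cf[t+1]
  ff <- if (n >= 2) !flag[-n] & !flag[-1] else logical(0)
  cff <- c(0L, cumsum(ff))                       # double-gaps starting in [1, t]
  vi <- integer(0)
  vj <- integer(0)
  for (i in seq_len(n)) {
    if (!flag[i]) next
    j <- i:n
    ok <- flag[j] &
      (cf[j + 1L] - cf[i] >= min_outliers) &          # enough flagged inside
      (j == i | cff[pmax(j, i)] - cff[i] == 0)        # no (t, t+1) gap inside
    vi <- c(vi, rep.int(i, sum(ok)))
    vj <- c(vj, j[ok])
  }
  valid <- cbind(vi, vj, deparse.level = 0)
  if (nrow(valid) == 0) return(valid)
  keep <- vapply(seq_len(nrow(valid)), function(k) {
    !any(valid[, 1] <= valid[k, 1] & valid[, 2] >= valid[k, 2] &
           (valid[, 1] < valid[k, 1] | valid[, 2] > valid[k, 2]))
  }, logical(1))
  valid[keep, , drop = FALSE][order(valid[keep, 1]), , drop = FALSE]
}

# Wrap a bare flag vector as a minimal calls tibble on a one-chromosome grid
# so exported stretch functions can run on it.
calls_from_flags <- function(flag, p = NULL, window_size = 5e5,
                             sample_id = "s") {
  n <- length(flag)
  if (is.null(p)) p <- ifelse(flag, -1, 0)
  tibble::tibble(sample_id = sample_id,
                 chrom = factor("chrA"),
                 start = (seq_len(n) - 1) * window_size,
                 end = seq_len(n) * window_size,
                 window = seq_len(n),
                 p = p, z = p, flag = flag)
}

# A gbs_counts object directly from a count vector on a given grid.
counts_from_vector <- function(counts, windows, sample_id = "s") {
  out <- tibble::as_tibble(windows)
  out$count <- as.integer(counts)
  structure(out, class = c("gbs_counts", class(tibble::tibble())),
            sample_id = sample_id, total_passing = sum(counts),
            n_skipped = 0L,
            window_size = attr(windows, "window_size"),
            epsilon = attr(windows, "epsilon"))
}
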