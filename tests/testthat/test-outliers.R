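profile_from_p <- function(p, sample_id = "s") {
  n <- length(p)
  tibble::tibble(sample_id = sample_id, chrom = factor("chrA"),
                 start = (seq_len(n) - 1) * 5e5, end = seq_len(n) * 5e5,
                 window = seq_len(n), p = p)
}

test_that("a gross outlier in a null profile is flagged with a huge score", {
  set.seed(101)
  p <- c(rnorm(1000), 50)
  calls <- call_outliers(profile_from_p(p))
  # verify against a direct median/MAD computation on the drawn sample
  z_direct <- (50 - median(p)) / (1.4826 * median(abs(p - median(p))))
  expect_equal(calls$z[1001], z_direct)
  expect_gt(abs(calls$z[1001]), qnorm(0.9999))
  expect_true(calls$flag[1001])
  expect_equal(attr(calls, "threshold"), qnorm(0.9999))
})

test_that("a constant profile has zero MAD, no flags, and warns", {
  expect_warning(calls <- call_outliers(profile_from_p(rep(1, 10))), "MAD")
  expect_false(any(calls$flag))
  expect_error(call_outliers(profile_from_p(numeric(0))), "empty")
})

test_that("flags are invariant under affine rescaling of the profile", {
  set.seed(102)
  p <- rnorm(500, sd = 2)
  p[c(17, 200)] <- c(30, -30)
  base <- call_outliers(profile_from_p(p))
  for (ab in list(c(3, 0), c(0.1, 5), c(7, -2))) {
    resc <- call_outliers(profile_from_p(ab[1] * p + ab[2]))
    expect_equal(resc$flag, base$flag)
    expect_equal(resc$z, base$z)
  }
})

test_that("raising the probability never adds flags; upper sidedness drops low outliers", {
  set.seed(103)
  p <- rnorm(2000)
  p[c(5, 500)] <- c(-20, 20)
  loose <- call_outliers(profile_from_p(p), prob = 0.99)
  strict <- call_outliers(profile_from_p(p), prob = 0.9999)
  expect_true(all(which(strict$flag) %in% which(loose$flag)))
  up <- call_outliers(profile_from_p(p), sidedness = "upper")
  expect_false(up$flag[5])
  expect_true(up$flag[500])
  two <- call_outliers(profile_from_p(p))
  expect_true(all(two$flag[c(5, 500)]))
})

test_that("stretch assembly follows the single-gap rule on the worked cases", {
  run1 <- find_stretches(calls_from_flags(c(TRUE, TRUE, TRUE)), 3)
  expect_equal(nrow(run1), 1)
  expect_equal(c(run1$start_window, run1$end_window, run1$n_outliers),
               c(1, 3, 3))

  run2 <- find_stretches(calls_from_flags(c(TRUE, FALSE, TRUE, TRUE)), 3)
  expect_equal(nrow(run2), 1)
  expect_equal(c(run2$start_window, run2$end_window, run2$n_outliers),
               c(1, 4, 3))

  run3 <- find_stretches(
    calls_from_flags(c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE)), 3)
  expect_equal(nrow(run3), 1)
  expect_equal(c(run3$start_window, run3$end_window, run3$n_outliers),
               c(4, 6, 3))

  expect_equal(nrow(find_stretches(calls_from_flags(rep(FALSE, 6)), 1)), 0)
})

test_that("stretch assembly matches the brute-force enumerator on random cases", {
  set.seed(104)
  for (rep in 1:60) {
    n <- sample(4:30, 1)
    flag <- runif(n) < 0.4
    for (m in 1:3) {
      got <- find_stretches(calls_from_flags(flag), m)
      want <- oracle_stretches(flag, m)
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$start_window, unname(want[, 1]))
      expect_equal(got$end_window, unname(want[, 2]))
    }
  }
})

test_that("stretches never cross chromosomes and satisfy their invariants", {
  calls <- dplyr::bind_rows(
    dplyr::mutate(calls_from_flags(c(TRUE, TRUE, TRUE, FALSE)),
                  chrom = factor("c1", levels = c("c1", "c2"))),
    dplyr::mutate(calls_from_flags(c(TRUE, TRUE, FALSE, FALSE)),
                  chrom = factor("c2", levels = c("c1", "c2")),
                  window = window + 4L))
  st <- find_stretches(calls, min_outliers = 2)
  expect_equal(nrow(st), 2)
  expect_equal(as.character(st$chrom), c("c1", "c2"))
  flags <- calls$flag
  for (i in seq_len(nrow(st))) {
    seg <- flags[st$start_window[i]:st$end_window[i]]
    expect_true(seg[1] && seg[length(seg)])
    expect_false(any(!seg[-length(seg)] & !seg[-1]))
    expect_gte(st$n_outliers[i], 2)
  }
})

test_that("raising min_outliers never adds stretches", {
  set.seed(105)
  flag <- runif(40) < 0.5
  prev <- nrow(find_stretches(calls_from_flags(flag), 1))
  for (m in 2:6) {
    cur <- nrow(find_stretches(calls_from_flags(flag), m))
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("the longest stretch maximises outliers with documented tie-breaks", {
  expect_equal(nrow(longest_stretch(find_stretches(
    calls_from_flags(rep(FALSE, 4)), 1))), 0)

  st <- tibble::tibble(sample_id = "s",
                       chrom = factor(c("c1", "c2"), levels = c("c1", "c2")),
                       start_window = c(1L, 10L), end_window = c(3L, 16L),
                       start = c(0, 0), end = c(1.5e6, 3.5e6),
                       n_outliers = c(3L, 7L), mean_p = c(-1, -1),
                       direction = "decreased")
  expect_equal(longest_stretch(st)$n_outliers, 7L)

  # tie on n_outliers: the larger bp span wins
  tie <- st
  tie$n_outliers <- c(5L, 5L)
  tie$end <- c(4e6, 6e6)
  expect_equal(longest_stretch(tie)$end, 6e6)
})

test_that("direction reflects the sign of the stretch-mean denoised value", {
  expect_equal(classify_direction(c(-1, 0.8, -0.05, 0)),
               c("decreased", "increased", "decreased", "decreased"))
  flags <- c(TRUE, TRUE, TRUE)
  up <- find_stretches(calls_from_flags(flags, p = c(0.7, 0.9, 0.8)), 3)
  expect_equal(up$direction, "increased")
  expect_equal(up$mean_p, 0.8)
  dn <- find_stretches(calls_from_flags(flags, p = c(-1, -1, -1)), 3)
  expect_equal(dn$direction, "decreased")
})

test_that("interval overlap statistics follow half-open interval arithmetic", {
  reg <- function(chrom, start, end) tibble::tibble(chrom, start, end)
  ident <- overlap_fraction(reg("c", 0, 10), reg("c", 0, 10))
  expect_equal(unlist(ident), c(fraction_of_annotated = 1, jaccard = 1))
  disj <- overlap_fraction(reg("c", 0, 10), reg("c", 20, 30))
  expect_equal(unlist(disj), c(fraction_of_annotated = 0, jaccard = 0))
  half <- overlap_fraction(reg("c", 0, 10), reg("c", 5, 15))
  expect_equal(half$fraction_of_annotated, 0.5)
  expect_equal(half$jaccard, 5 / 15)
  other <- overlap_fraction(reg("c1", 0, 10), reg("c2", 0, 10))
  expect_equal(unlist(other), c(fraction_of_annotated = 0, jaccard = 0))
  expect_error(overlap_fraction(reg("c", 0, 10), reg("c", 5, 5)), "length")
})

test_that("outlier frequency uses the inclusive at-least threshold", {
  n_samples <- 100
  calls <- purrr::map_dfr(seq_len(n_samples), function(i) {
    f <- c(i <= 3, i <= 2, FALSE)
    calls_from_flags(f, sample_id = sprintf("s%03d", i))
  })
  fs <- frequency_summary(calls, threshold_fraction = 0.03)
  expect_equal(fs$n_flagged, c(3L, 2L, 0L))
  expect_equal(fs$fraction, c(0.03, 0.02, 0))
  expect_equal(fs$robust, c(TRUE, FALSE, FALSE))  # 3/100 is in, 2/100 is out
  expect_equal(attr(fs, "n_samples"), n_samples)

  none <- frequency_summary(
    purrr::map_dfr(1:4, ~calls_from_flags(rep(FALSE, 3),
                                          sample_id = paste0("s", .x))),
    threshold_fraction = 0.03)
  expect_false(any(none$robust))

  bad <- dplyr::bind_rows(calls_from_flags(c(TRUE, FALSE), sample_id = "a"),
                          calls_from_flags(c(TRUE, FALSE, TRUE),
                                           sample_id = "b"))
  expect_error(frequency_summary(bad, 0.03), "grid")
})
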