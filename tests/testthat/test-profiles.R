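gw4 <- build_windows(c(c1 = 1.5e6, c2 = 0.5e6), 5e5)  # 4 windows

test_that("normalization scales to counts per million passing reads", {
  gw3 <- build_windows(c(c1 = 1.5e6), 5e5)
  ct <- counts_from_vector(c(2L, 3L, 5L), gw3, "A")  # total_passing 10
  norm <- normalize_counts(ct)
  expect_equal(norm$c, c(200000, 300000, 500000))
  expect_equal(sum(norm$c), 1e6)

  empty <- counts_from_vector(c(0L, 0L, 0L), gw3, "Z")
  expect_error(normalize_counts(empty), "no passing reads")
})

test_that("reference modes: ancestor verbatim, per-window median", {
  mk <- function(id, v) normalize_counts(counts_from_vector(v, gw4, id))
  s <- list(mk("A", c(1, 2, 3, 4) * 100),
            mk("B", c(3, 4, 1, 2) * 100),
            mk("C", c(5, 6, 2, 0) * 100))
  med <- build_reference(s, "median")
  expect_equal(med$r, apply(cbind(s[[1]]$c, s[[2]]$c, s[[3]]$c), 1,
                            stats::median))
  anc <- build_reference(s, "ancestor", ancestor_id = "B")
  expect_equal(anc$r, s[[2]]$c)
  expect_equal(attr(anc, "source"), "B")
  expect_error(build_reference(s, "ancestor", ancestor_id = "nope"),
               "unknown")
  expect_error(build_reference(list(), "median"), "no samples")

  # even number of samples: mean of the two central order statistics
  s4 <- list(mk("A", c(1, 10, 0, 0)), mk("B", c(2, 20, 0, 0)),
             mk("C", c(3, 30, 0, 0)), mk("D", c(4, 40, 0, 0)))
  med4 <- build_reference(s4, "median")
  expect_equal(med4$r[1:2], c((s4[[2]]$c[1] + s4[[3]]$c[1]) / 2,
                              (s4[[2]]$c[2] + s4[[3]]$c[2]) / 2))
})

test_that("median of an odd collection picks an observed value per window", {
  set.seed(21)
  mk <- function(id) {
    v <- rpois(4, 50)
    normalize_counts(counts_from_vector(v + 1L, gw4, id))
  }
  s <- lapply(letters[1:5], mk)
  med <- build_reference(s, "median")
  cs <- sapply(s, function(x) x$c)
  for (i in 1:4) expect_true(med$r[i] %in% cs[i, ])
})

test_that("log ratio reproduces worked values and is antisymmetric", {
  mk <- function(v) {
    x <- counts_from_vector(rep(1L, 4), gw4, "x")
    x$c <- v
    x
  }
  a <- mk(c(3, 0, 5, 1))
  expect_equal(log_ratio(mk(c(3, 0, 7, 2)), c(3, 0, 7, 2), epsilon = 1)$d,
               rep(0, 4))
  expect_equal(log_ratio(mk(c(3, 3, 3, 3)), c(1, 1, 1, 1), epsilon = 1)$d,
               rep(1, 4))   # log2(4/2)
  expect_equal(log_ratio(mk(c(0, 0, 0, 0)), c(3, 3, 3, 3), epsilon = 1)$d,
               rep(-2, 4))  # log2(1/4)
  b_vals <- c(9, 2, 0, 4)
  ab <- log_ratio(a, b_vals, epsilon = 0.5)$d
  ba <- log_ratio(mk(b_vals), a$c, epsilon = 0.5)$d
  expect_equal(ab, -ba)
  expect_true(all(is.finite(ab)))
  expect_error(log_ratio(a, c(1, 2), epsilon = 1), "length")
  expect_error(log_ratio(a, c(1, 2, 3, 4), epsilon = 0), "epsilon")
})

test_that("rolling mean smooths per chromosome with truncated edges", {
  gw <- build_windows(c(c1 = 2.5e6, c2 = 1e6), 5e5)  # 5 + 2 windows
  prof <- tibble::as_tibble(gw)
  prof$d <- c(0, 0, 5, 0, 0, 7, 7)
  sm <- denoise(prof, k = 5)
  expect_equal(sm$p[3], 1)            # full centered window
  expect_equal(sm$p[1], 5 / 3)        # edge truncated to 3 values
  expect_equal(sm$p[2], 5 / 4)        # edge truncated to 4 values
  expect_equal(sm$p[6:7], c(7, 7))    # c2 untouched by c1 values
  expect_error(denoise(prof, k = 4), "odd")

  # idempotent on constants, linear in the signal
  prof$d <- rep(2, 7)
  expect_equal(denoise(prof, 5)$p, rep(2, 7))
  set.seed(5)
  prof$d <- rnorm(7)
  scaled <- prof
  scaled$d <- 3 * prof$d
  expect_equal(denoise(scaled, 3)$p, 3 * denoise(prof, 3)$p)
})

test_that("identical samples give an identical median reference and zero profiles", {
  v <- c(10L, 20L, 30L, 40L)
  s <- lapply(c("A", "B", "C"), function(id) counts_from_vector(v, gw4, id))
  prof <- coverage_profiles(s, gw4, reference = "median")
  expect_equal(prof$d, rep(0, 12))
  expect_equal(prof$p, rep(0, 12))
  expect_equal(prof$r, prof$c)
})

test_that("leave-one-out median excludes the sample from its own reference", {
  mk <- function(id, v) counts_from_vector(v, gw4, id)
  s <- list(mk("A", c(100L, 0L, 0L, 0L)),
            mk("B", c(0L, 100L, 0L, 0L)),
            mk("C", c(0L, 0L, 100L, 0L)))
  loo <- coverage_profiles(s, gw4, leave_one_out = TRUE)
  a <- dplyr::filter(loo, sample_id == "A")
  # A's reference at window 1 is the median of B and C (= 0), not of all three
  expect_equal(a$r[1], 0)
  full <- coverage_profiles(s, gw4)
  expect_equal(dplyr::filter(full, sample_id == "A")$r[1], 0)  # median of 3
  expect_equal(attr(loo, "reference_mode"), "median_loo")
})
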