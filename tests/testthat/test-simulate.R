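small_spec <- function(...) {
  simulation_spec(chrom_lengths = c(c1 = 1e7, c2 = 1e7), window_size = 5e5,
                  n_samples = 3, library_size_mean = 1e5,
                  library_size_cv = 0, seed = 42, ...)
}

test_that("baseline landscape is a normalised telomere-high bowl", {
  gw <- build_windows(c(c1 = 1e7), 5e5)
  flat <- baseline_landscape(gw, contrast = 0)
  expect_equal(flat, rep(1 / 20, 20))

  w <- baseline_landscape(gw, contrast = 1.5, centromere = 0.5)
  expect_equal(sum(w), 1)
  expect_true(all(w > 0))
  expect_gt(w[1], w[10])    # telomeric window beats centromeric window
  expect_gt(w[20], w[10])
  # larger contrast, larger telomere/centromere ratio
  w2 <- baseline_landscape(gw, contrast = 3)
  expect_gt(w2[1] / w2[10], w[1] / w[10])
})

test_that("events rescale exactly the covered window fractions", {
  gw <- build_windows(c(c1 = 1e7), 5e5)
  w <- rep(0.002, 20)
  ev <- function(start, end, kind = "introgression", factor = 0.3) {
    tibble::tibble(chrom = "c1", start = start, end = end,
                   kind = kind, factor = factor)
  }
  expect_equal(apply_events(w, ev(0, 1e7, factor = 1), gw), w)
  del <- apply_events(w, ev(2.5e6, 5e6, "deletion", 0), gw)
  expect_equal(del[6:10], rep(0, 5))
  expect_equal(del[-(6:10)], w[-(6:10)])

  one <- apply_events(w, ev(5e5, 1e6, factor = 0.3), gw)
  expect_equal(one[2], 0.002 * 0.3)

  partial <- apply_events(w, ev(0, 2.5e5, "deletion", 0), gw)
  expect_equal(partial[1], 0.002 * 0.5)  # half the window deleted

  both <- dplyr::bind_rows(ev(0, 1e6, "deletion", 0),
                           ev(5e5, 2e6, "duplication", 2))
  expect_error(apply_events(w, both, gw), "unsupported")
  apart <- dplyr::bind_rows(ev(0, 1e6, "deletion", 0),
                            ev(5e6, 6e6, "duplication", 2))
  expect_silent(apply_events(w, apart, gw))
})

test_that("count draws are reproducible and conserve expectations", {
  gw <- build_windows(c(c1 = 1e7), 5e5)
  w <- baseline_landscape(gw, contrast = 1)
  expect_equal(draw_counts(gw, rep(0, 20), 1e5)$count, rep(0L, 20))

  set.seed(9)
  a <- draw_counts(gw, w, 5e5)
  set.seed(9)
  b <- draw_counts(gw, w, 5e5)
  expect_identical(a$count, b$count)
  expect_identical(attr(a, "total_passing"), sum(a$count))

  # the total is Poisson(library_size); stay within 4 SD over repeated draws
  set.seed(10)
  totals <- replicate(20, sum(draw_counts(gw, w, 5e5)$count))
  expect_true(all(abs(totals - 5e5) < 4 * sqrt(5e5)))

  set.seed(11)
  nb <- draw_counts(gw, w, 5e5, noise = "nb", dispersion = 0.5)
  expect_true(all(nb$count >= 0))
})

test_that("a seeded collection is deterministic and carries its truth", {
  ev <- tibble::tibble(sample_id = "S02", chrom = "c1", start = 2e6, end = 6e6,
                       kind = "deletion", factor = 0)
  s1 <- simulate_collection(small_spec(events = ev))
  s2 <- simulate_collection(small_spec(events = ev))
  expect_identical(lapply(s1$samples, `[[`, "count"),
                   lapply(s2$samples, `[[`, "count"))
  expect_named(s1$samples, c("S01", "S02", "S03"))
  expect_equal(s1$truth$kind, "deletion")
  # the deleted windows of the carrier are empty; other samples are not
  del_win <- which(as.character(s1$windows$chrom) == "c1" &
                     s1$windows$start >= 2e6 & s1$windows$end <= 6e6)
  expect_equal(sum(s1$samples$S02$count[del_win]), 0L)
  expect_gt(sum(s1$samples$S01$count[del_win]), 0L)
})

test_that("methylation shifts draw stochastic per-window retention", {
  gw <- build_windows(c(c1 = 1e7), 5e5)
  w <- rep(0.002, 20)
  ev <- tibble::tibble(chrom = "c1", start = 0, end = 1e7,
                       kind = "methylation_shift", factor = 0.4)
  set.seed(12)
  shifted <- apply_events(w, ev, gw)
  expect_true(all(shifted >= 0 & shifted <= w))
  expect_gt(stats::sd(shifted / w), 0)           # window-wise, not constant
  expect_lt(abs(mean(shifted / w) - 0.4), 0.15)  # mean retention near factor
})

test_that("events out of range are rejected by the spec constructor", {
  expect_error(simulation_spec(
    chrom_lengths = c(c1 = 1e6), events = tibble::tibble(
      sample_id = "S01", chrom = "c1", start = 0, end = 2e6,
      kind = "deletion", factor = 0)))
  expect_error(simulation_spec(chrom_lengths = c(c1 = -1)))
})

test_that("an event-free collection almost never yields long outlier stretches", {
  clean <- 0L
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    sim <- simulate_collection(simulation_spec(n_samples = 8, seed = 3000 + r))
    prof <- coverage_profiles(sim$samples, sim$windows)
    long <- find_stretches(call_outliers(prof), min_outliers = 30)
    if (nrow(long) == 0) clean <- clean + 1L
  }
  expect_gte(clean, ceiling(0.95 * n_rep))
})
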