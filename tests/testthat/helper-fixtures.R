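# Hand-built alignment fixture on a tiny two-chromosome genome (cA 2 Mb,
# cB 1 Mb, 500-kb windows -> 6 windows).  The expected per-window counts are
# worked out by hand in the comments: reads r04 (secondary), r05 (MAPQ 19),
# r06 (only 20 non-clipped bases), r08 (supplementary) and r09 (unmapped)
# must be excluded; r02/r03 probe the half-open window boundary.
fixture_reads <- function() {
  tibble::tribble(
    ~qname, ~flag, ~chrom,   ~pos, ~mapq,    ~cigar,
    "r01",     0L,   "cA",      0,   60L,    "100M",  # win 1
    "r02",    16L,   "cA", 499999,   60L,    "100M",  # win 1 (last bp)
    "r03",     0L,   "cA", 500000,   60L,    "100M",  # win 2 (half-open)
    "r04",   256L,   "cA", 700000,   60L,    "100M",  # secondary: excluded
    "r05",     0L,   "cA", 800000,   19L,    "100M",  # MAPQ 19: excluded
    "r06",     0L,   "cA", 900000,   60L,  "80S20M",  # overclipped: excluded
    "r07",     0L,   "cA",    1e6,   60L,  "70S30M",  # win 3 (30 bases kept)
    "r08",  2048L,   "cA",   15e5,   60L,    "100M",  # supplementary: excl.
    "r09",     4L,   "cA",      0,    0L,       "*",  # unmapped: excluded
    "r10",     0L,   "cB",    100,   20L,    "100M",  # win 5, MAPQ boundary
    "r11",     0L,   "cB",    6e5,   60L,    "100M")  # win 6
}
fixture_expected <- c(2L, 1L, 1L, 0L, 1L, 1L)
fixture_lens <- c(cA = 2e6, cB = 1e6)

# The three-sample locus fixture behind the presence/absence partition tests:
# read-start loci in a 1-kb region with hand-assigned per-sample counts.
fixture_locus_reads <- function() {
  mk <- function(pos, n, sample_id) {
    tibble::tibble(sample_id = sample_id, chrom = "c1", pos = rep(pos, n),
                   flag = 0L, mapq = 60L, cigar = "64M")
  }
  plan <- tibble::tribble(
    ~pos,  ~A, ~B, ~C,
    1000,   4,  4,  4,   # A&B&C, combined 12
    1010,   6,  5,  0,   # A&B,   combined 11
    1020,   7,  0,  6,   # A&C,   combined 13
    1030,   0,  9,  8,   # B&C,   combined 17
    1040,  12,  0,  0,   # A,     combined 12
    1050,   0, 13,  0,   # B,     combined 13
    1060,   0,  0, 14,   # C,     combined 14
    1070,  15,  2,  1,   # A&B&C, combined 18
    1080,   5,  5,  0,   # combined exactly 10: retained (A&B)
    1090,   5,  4,  0)   # combined 9: dropped
  purrr::pmap_dfr(plan, function(pos, A, B, C) {
    dplyr::bind_rows(mk(pos, A, "A"), mk(pos, B, "B"), mk(pos, C, "C"))
  })
}
fixture_locus_region <- tibble::tibble(chrom = "c1", start = 1000, end = 2000)
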