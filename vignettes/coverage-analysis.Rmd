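---
title: "GBS coverage analysis: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GBS coverage analysis: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbscov)
```

## The model

Genotyping-by-sequencing (GBS) reads begin at restriction-enzyme cut sites,
so the density of read starts along a reference genome is a reproducible
fingerprint of a genotype. Large chromosomal modifications perturb that
fingerprint regionally: a deletion or an introgression from a related
species (whose sequence diverges from the reference, and whose methylation
state may silence methylation-sensitive cut sites) depresses coverage over
megabases, while a duplication elevates it. `gbscov` detects such regions by
comparing each sample's windowed read-start density against an expectation
and flagging windows where the deviation is extreme relative to the
sample's own genome-wide noise level.

The processing chain, per sample $s$ with $N$ windows of width $w$:

$$c_i = \frac{\text{reads starting in window } i}{\text{total passing reads}} \times 10^6,
\qquad d_i = \log_2\!\frac{c_i + \varepsilon}{r_i + \varepsilon},
\qquad \varepsilon = \frac{10^6}{N},$$

followed by a centered rolling mean of width $k$ within each chromosome
(yielding $p_i$), robust standardization
$z_i = (p_i - \mathrm{median}(p)) / (1.4826\,\mathrm{MAD}(p))$ over the
whole genome, flagging at $|z_i| > \Phi^{-1}(q)$, and assembly of flagged
windows into gap-tolerant stretches.

Key assumptions: (i) library size is the only global difference between
samples — normalization to counts per million removes it; (ii) the
within-genome coverage landscape (telomere-high, centromere-low in cereals)
is shared across samples, so it cancels in the ratio against the reference;
(iii) most of any sample's genome is unmodified, so the genome-wide median
and MAD of $p$ estimate the null location and scale even in carriers
(median/MAD tolerate up to 50% contamination, far above any realistic
modified fraction); (iv) read starts are approximately independent given
the landscape, so window counts are roughly Poisson.

## Parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `window_size` | 500,000 | bp | resolves multi-Mb events at genebank read depths (~0.5M reads → ~350 reads/window on a 4.2 Gb-scaled grid); smaller windows trade resolution for noise |
| `min_mapq` | 20 | PHRED | discards ambiguous placements (error prob > 1%) |
| `min_aligned_bases` | 30 | bases | excludes overclipped alignments whose placement rests on a short match |
| `prob` | 0.9999 | quantile | two-sided threshold $\Phi^{-1}(0.9999) \approx 3.719$; at 1,400–4.3M windows per genome this keeps expected false flags per sample at $2 \times 10^{-4} N$ |
| `k` | 5 | windows | smooths isolated noisy windows while keeping ≥ 2.5 Mb events visible |
| `min_outliers` | 3 | windows | the smallest run that is unlikely by chance after smoothing |
| `long_min_outliers` | 30 | windows | collection-scale screening (≥ 15 Mb at 500 kb), robust to shallow libraries |
| `min_reads` | 100,000 | reads | below this, window counts are too sparse for stable ratios; strictly-less-than is discarded |
| `threshold_fraction` | 0.03 | fraction | "robust" windows recur in at least this share of a collection |

The epsilon pseudocount uses the genome-wide $N$ (one $\varepsilon$ for the
whole genome, the expected reads per window for a million-read library),
not a per-chromosome value: it plays the role of a global prior count and
keeping it constant preserves comparability of $d$ across chromosomes.

## Reference profiles

With a known ancestor, $r$ is that sample's normalized counts verbatim.
Without pedigree information, $r_i$ is the per-window median across the
collection — an estimator of the "typical" genotype that is insensitive to
any single carrier. The median includes the query sample by default
(`leave_one_out = FALSE`); with tens of samples the self-contribution is
negligible, and including it keeps one shared reference for the whole
collection (cheaper, and byte-reproducible regardless of sample order). For
an even number of samples the median is the mean of the two central order
statistics, the standard convention. The acceptance suite verifies that
median-reference detection localizes events essentially identically to a
true-ancestor reference (Jaccard > 0.9 in our simulations).

## Outlier scoring and stretch rules

Scoring is genome-wide per sample; stretch assembly is per chromosome.
Two-sided flagging is the default because both decreased (introgression,
deletion, methylation gain) and increased (duplication) coverage are
biologically meaningful; `sidedness = "upper"` is available where only
amplifications are of interest. If a sample's MAD is zero (degenerate,
e.g. a sample compared against itself) no flags are emitted and a warning
is raised rather than dividing by zero.

A stretch is a maximal run in which at most one of two consecutive windows
is unflagged; two consecutive unflagged windows always terminate it, and a
stretch must start and end on flagged windows. `min_outliers` counts
*flagged* windows, not total span — the stricter of the two possible
readings, and the two coincide for gap-free runs. The stretch finder is
verified exhaustively against a brute-force interval enumerator over all
$2^{14}$ flag vectors.

Ties and degenerate cases are resolved deterministically: the "longest"
stretch maximizes flagged windows, then bp span, then chromosome order,
then start coordinate; a stretch whose mean $p$ is exactly zero is
classified `decreased`. Overlap with annotated regions is reported both as
the fraction of the annotation covered (the headline number) and as the
Jaccard index, which also penalizes over-calling.

## What the simulator emulates — and what it does not

`simulate_collection()` draws per-window read-start counts from a Poisson
(optionally negative-binomial) distribution around a shared landscape:
a smooth per-chromosome bowl, $\exp(\text{contrast} \cdot u)$ with $u$ the
squared relative distance from a configurable centromere, normalized
genome-wide — reproducing the telomere-high/centromere-low trend the method
must tolerate. Events multiply the expected coverage of the covered window
fractions: factor 0 for deletions, < 1 for introgressions, > 1 for
duplications, and a Beta-distributed (mean = factor, concentration 10)
per-window retention for methylation shifts, emulating locus-wise dropout.
Library sizes are log-normal across samples with configurable CV.

Defaults encode the study conditions the package is tested under: seven
100-Mb chromosomes with 500-kb windows (1,400 windows — a 4.2 Gb cereal
genome scaled down 30-fold at fixed window size), 30 samples, 500,000-read
libraries (the depth at which genebank GBS collections are screened),
contrast 1, introgression factors 0.1–0.5 (0.3 in the recovery tests, an
engineering choice consistent with the locus-sharing drop observed in real
introgressed regions), duplication factor 1.8.

The simulator does *not* model: restriction-site positions or sequence
(counts are drawn at window, not locus, resolution), mapping artefacts
(repeats, paralogy, reference errors — real data show recurrent telomeric
outliers from these), GC/mappability bias, shared pedigree structure among
samples, or partially heterozygous events. Passing the recovery tests
therefore demonstrates the statistical machinery under the stated noise
model, not robustness to every artefact of real alignments; the alignment
path itself is exercised separately on hand-built SAM/BAM fixtures with
known flags, MAPQ, CIGAR clipping and window-boundary reads.

## Numerical choices

- Rolling-mean edges use truncated (shrinking) windows, so output length
  equals input length and chromosome ends are averages of the available
  ≤ $k$ values; smoothing never crosses a chromosome boundary.
- "Not overclipped with at least 30 bases" is interpreted as ≥ 30
  non-clipped query bases (read length minus soft- plus hard-clipped
  bases); the threshold is configurable.
- Both mates of a pair are counted when each passes the filter (a
  first-in-pair-only switch exists). Duplicate-flagged reads are *not*
  excluded — GBS read starts are constrained to cut sites, so PCR-duplicate
  flags are uninformative there. Secondary and supplementary alignments are
  both excluded under the primary-alignment rule.
- All profile arithmetic is double precision; nothing is rounded before
  scoring. The flagging threshold is computed from `qnorm(prob)` at run
  time, never hard-coded.
- Coordinates are 0-based half-open everywhere internally and in BED
  output; human-readable reports render Mb.

## Problem sizes in the test suite

The packaged tests run the recovery analysis at 20 seeded replicates of the
default 30-sample × 1,400-window collection, the null calibration on a
$10^6$-window profile, and the exhaustive stretch-finder comparison on all
$2^{14} \times 3$ cases — sizes chosen so the full suite completes in about
two minutes on a single core while keeping every estimate's Monte-Carlo
error well inside the asserted margins.

## Limitations

Resolution is bounded by the window size: events ≪ 500 kb are invisible at
genebank depths. Balanced rearrangements (inversions, reciprocal
translocations) do not change coverage and cannot be detected. Regions
absent from the reference genome are likewise invisible. The median
reference assumes modifications are rare at each locus across the
collection; a variant shared by most samples becomes the expectation and
the *non*-carriers get flagged instead. Donor identity cannot be assigned
from coverage alone — that requires orthogonal (e.g. SNP) evidence.

The command-line front end (`inst/cli/gbscov.R`) deliberately exposes only
counting, simulation and the end-to-end run; per-stage operations are the
package's tidy functions, which compose better in R than through
intermediate files.
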