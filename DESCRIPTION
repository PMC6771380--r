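Package: gbscov
Title: Detecting Large Chromosomal Modifications from Genotyping-by-Sequencing Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects large chromosomal modifications (alien introgressions,
    deletions, duplications, and methylation shifts) from the read-start
    coverage of genotyping-by-sequencing (GBS) data.  Reads are filtered for
    primary alignment, mapping quality and clipping, counted in fixed
    non-overlapping genomic windows, normalised to counts per million, and
    compared to an ancestor or per-window median reference through a
    pseudocount-stabilised log2 ratio.  A per-chromosome rolling mean denoises
    each profile before robust MAD-based outlier scoring flags windows of
    unexpected coverage; flagged windows are assembled into gap-tolerant
    stretches, classified by direction, and summarised across collections.
    A synthetic-data generator with known ground-truth events makes every
    stage testable, and tidy tibble interfaces with ggplot2 plotting support
    interactive exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    zoo
Suggests:
    GenomicAlignments,
    Rsamtools,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
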