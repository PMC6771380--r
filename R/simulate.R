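#' Specify a synthetic GBS coverage simulation
#'
#' Defines the genome, sampling depth and ground-truth chromosomal
#' modifications for a simulated GBS collection.  The defaults emulate a
#' barley-like setting scaled to desk size: seven 100-Mb chromosomes on a
#' 500-kb window grid (1,400 windows), 30 samples, and a mean library of
#' 500,000 passing reads — matching the read depth at which real genebank
#' collections are screened.
#'
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param window_size Window width in bp (default 500,000).
#' @param n_samples Number of samples (default 30).
#' @param library_size_mean Mean number of passing reads per sample
#'   (default 500,000).
#' @param library_size_cv Coefficient of variation of the per-sample library
#'   size, log-normal across samples (default 0.3; 0 for identical depth).
#' @param contrast Telomere/centromere coverage contrast of the baseline
#'   landscape (default 1; 0 gives a flat genome).
#' @param centromere Relative centromere position within each chromosome
#'   (default 0.5).
#' @param noise `"poisson"` (default) or `"nb"` for negative-binomial
#'   overdispersion.
#' @param dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); only used with `noise = "nb"`.
#' @param events Ground-truth modifications: a data frame with columns
#'   `sample_id`, `chrom`, `start`, `end`, `kind` (one of `deletion`,
#'   `duplication`, `introgression`, `methylation_shift`) and `factor`
#'   (multiplier on expected coverage: 0 for deletions, e.g. 1.5–2 for
#'   duplications, 0.1–0.5 for introgressions, mean retention for
#'   methylation shifts).  `NULL` for an event-free null collection.
#' @param seed Integer seed; fixed seed gives identical output.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(chrom_lengths = stats::setNames(rep(1e8, 7),
                                                            paste0("chr", 1:7, "H")),
                            window_size = 500000,
                            n_samples = 30,
                            library_size_mean = 500000,
                            library_size_cv = 0.3,
                            contrast = 1,
                            centromere = 0.5,
                            noise = c("poisson", "nb"),
                            dispersion = 0,
                            events = NULL,
                            seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(all(chrom_lengths > 0), window_size > 0, n_samples >= 1,
            library_size_mean > 0, library_size_cv >= 0,
            centromere > 0, centromere < 1, dispersion >= 0)
  if (!is.null(events)) {
    events <- tibble::as_tibble(events)
    stopifnot(all(c("sample_id", "chrom", "start", "end", "kind", "factor")
                  %in% names(events)))
    stopifnot(all(events$kind %in% c("deletion", "duplication",
                                     "introgression", "methylation_shift")),
              all(events$factor >= 0),
              all(events$start >= 0),
              all(events$end <= chrom_lengths[as.character(events$chrom)]))
  }
  structure(list(chrom_lengths = chrom_lengths, window_size = window_size,
                 n_samples = n_samples, library_size_mean = library_size_mean,
                 library_size_cv = library_size_cv, contrast = contrast,
                 centromere = centromere, noise = noise,
                 dispersion = dispersion, events = events, seed = seed),
            class = "simulation_spec")
}

#' Baseline expected coverage landscape
#'
#' GBS coverage along real cereal chromosomes is high near the telomeres and
#' low around the centromere.  The baseline emulates this with a smooth bowl
#' per chromosome: with `u` the squared relative distance of a window
#' midpoint from the centromere (0 at the centromere, 1 at the farther
#' telomere), the raw weight is `exp(contrast * u)`, normalised to sum to one
#' over the genome.  `contrast = 0` gives uniform weights.
#'
#' @param windows A `gbs_windows` grid.
#' @param contrast Non-negative telomere/centromere contrast.
#' @param centromere Relative centromere position in (0, 1).
#' @return Numeric vector of positive per-window weights summing to 1,
#'   aligned to `windows`.
#' @export
baseline_landscape <- function(windows, contrast = 1, centromere = 0.5) {
  stopifnot(inherits(windows, "gbs_windows"), contrast >= 0)
  lens <- attr(windows, "chrom_lengths")
  len <- unname(lens[as.character(windows$chrom)])
  cen <- centromere * len
  mid <- (windows$start + windows$end) / 2
  u <- ((mid - cen) / pmax(cen, len - cen))^2
  w <- exp(contrast * pmin(u, 1))
  w / sum(w)
}

#' Apply ground-truth modification events to a coverage landscape
#'
#' Every window fully inside an event region has its weight multiplied by the
#' event's factor; windows partially covered are scaled in proportion to the
#' covered fraction (`w * (1 - f + f * factor)` for covered fraction `f`), so
#' deletions (factor 0) zero exactly the covered portion.  For
#' `methylation_shift` events the factor is stochastic per window, drawn from
#' a Beta distribution with mean equal to the event's `factor` (concentration
#' 10), emulating locus-wise methylation dropout; draws use the current RNG
#' state.
#'
#' Overlapping events of different kinds on the same sample are not supported
#' and are rejected.
#'
#' @param weights Per-window weights (e.g. from [baseline_landscape()]).
#' @param events A data frame with columns `chrom`, `start`, `end`, `kind`,
#'   `factor` (one sample's events).
#' @param windows The `gbs_windows` grid.
#' @return Modified weight vector (not renormalised: events change total
#'   expected coverage, as real modifications do).
#' @export
apply_events <- function(weights, events, windows) {
  stopifnot(length(weights) == nrow(windows), all(weights >= 0))
  if (is.null(events) || nrow(events) == 0) return(weights)
  events <- tibble::as_tibble(events)

  touched_by <- lapply(seq_len(nrow(events)), function(i) {
    which(as.character(windows$chrom) == as.character(events$chrom[i]) &
            windows$end > events$start[i] & windows$start < events$end[i])
  })
  if (nrow(events) > 1) {
    for (i in seq_len(nrow(events) - 1)) {
      for (j in seq(i + 1, nrow(events))) {
        if (events$kind[i] != events$kind[j] &&
            length(intersect(touched_by[[i]], touched_by[[j]])) > 0) {
          stop("overlapping events of different kinds (",
               events$kind[i], " vs ", events$kind[j], ") are unsupported",
               call. = FALSE)
        }
      }
    }
  }

  for (i in seq_len(nrow(events))) {
    idx <- touched_by[[i]]
    if (length(idx) == 0) next
    cov <- pmax(0, pmin(windows$end[idx], events$end[i]) -
                  pmax(windows$start[idx], events$start[i]))
    f <- cov / (windows$end[idx] - windows$start[idx])
    fac <- if (events$kind[i] == "methylation_shift") {
      m <- min(max(events$factor[i], 1e-6), 1 - 1e-6)
      stats::rbeta(length(idx), 10 * m, 10 * (1 - m))
    } else {
      rep(events$factor[i], length(idx))
    }
    weights[idx] <- weights[idx] * (1 - f + f * fac)
  }
  weights
}

#' Draw window read-start counts from a coverage landscape
#'
#' Counts are drawn independently per window, Poisson with mean
#' `library_size * weight` (or negative binomial with that mean and the
#' configured dispersion).
#'
#' @param windows A `gbs_windows` grid.
#' @param weights Non-negative per-window weights.
#' @param library_size Expected total number of passing reads.
#' @param noise `"poisson"` or `"nb"`.
#' @param dispersion Negative-binomial dispersion (ignored for Poisson).
#' @param sample_id Sample identifier for the result.
#' @return A `gbs_counts` tibble (see [count_reads()]).
#' @export
draw_counts <- function(windows, weights, library_size,
                        noise = c("poisson", "nb"), dispersion = 0,
                        sample_id = "sim") {
  noise <- match.arg(noise)
  stopifnot(inherits(windows, "gbs_windows"),
            length(weights) == nrow(windows), all(weights >= 0))
  mu <- library_size * weights
  counts <- if (noise == "poisson" || dispersion == 0) {
    stats::rpois(length(mu), mu)
  } else {
    stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  }
  out <- tibble::as_tibble(windows)
  out$count <- as.integer(counts)
  structure(out,
            class = c("gbs_counts", class(tibble::tibble())),
            sample_id = sample_id,
            total_passing = sum(counts),
            n_skipped = 0L,
            window_size = attr(windows, "window_size"),
            epsilon = attr(windows, "epsilon"))
}

#' Simulate a GBS collection with known ground truth
#'
#' Builds the window grid and baseline landscape, applies each sample's
#' ground-truth events, draws per-sample library sizes (log-normal with the
#' configured mean and CV) and window counts, and returns everything needed
#' to run and verify the detection pipeline.
#'
#' @param spec A [simulation_spec()].
#' @return A list of class `gbs_simulation` with elements `windows`
#'   (`gbs_windows`), `samples` (list of `gbs_counts`, ids `S01`, `S02`, ...),
#'   `truth` (the event tibble, possibly `NULL`), `baseline` (weights) and
#'   `spec`.
#' @export
simulate_collection <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  windows <- build_windows(spec$chrom_lengths, spec$window_size)
  base <- baseline_landscape(windows, spec$contrast, spec$centromere)
  ids <- sprintf("S%02d", seq_len(spec$n_samples))

  sdlog <- sqrt(log(1 + spec$library_size_cv^2))
  lib <- stats::rlnorm(spec$n_samples,
                       meanlog = log(spec$library_size_mean) - sdlog^2 / 2,
                       sdlog = sdlog)

  samples <- lapply(seq_along(ids), function(i) {
    ev <- NULL
    if (!is.null(spec$events)) {
      ev <- dplyr::filter(spec$events, .data$sample_id == ids[i])
    }
    w <- apply_events(base, ev, windows)
    draw_counts(windows, w, lib[i], noise = spec$noise,
                dispersion = spec$dispersion, sample_id = ids[i])
  })
  names(samples) <- ids
  structure(list(windows = windows, samples = samples, truth = spec$events,
                 baseline = base, spec = spec),
            class = "gbs_simulation")
}

#' Write a small SAM file with hand-placed reads
#'
#' Emits a valid plain-text SAM (header plus one line per read) so the
#' alignment-counting path can be exercised end to end on a tiny genome;
#' convert with `Rsamtools::asBam()` where a BAM is needed.
#'
#' @param reads A data frame with columns `qname`, `flag`, `chrom`, `pos`
#'   (0-based; written as 1-based POS), `mapq`, `cigar` and optionally `seq`.
#' @param chrom_lengths Named vector of reference sequence lengths.
#' @param path Output file path (conventionally `.sam`).
#' @return The path, invisibly.
#' @export
write_sam <- function(reads, chrom_lengths, path) {
  reads <- tibble::as_tibble(reads)
  stopifnot(all(c("qname", "flag", "chrom", "pos", "mapq", "cigar")
                %in% names(reads)))
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  seq <- if ("seq" %in% names(reads)) reads$seq else {
    # SEQ must span the full query including soft clips (ops M, I, S, =, X)
    n <- vapply(reads$cigar, function(cg) {
      if (!grepl("^([0-9]+[MIDNSHP=X])+$", cg)) return(10L)
      lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
      ops <- regmatches(cg, gregexpr("[MIDNSHP=X]", cg))[[1]]
      max(sum(lens[ops %in% c("M", "I", "S", "=", "X")]), 1L)
    }, integer(1), USE.NAMES = FALSE)
    vapply(n, function(k) paste(rep("A", k), collapse = ""), character(1))
  }
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                   reads$qname, as.integer(reads$flag),
                   as.character(reads$chrom), as.integer(reads$pos) + 1L,
                   as.integer(reads$mapq), reads$cigar, seq)
  ord <- order(match(as.character(reads$chrom), names(chrom_lengths)),
               reads$pos)
  writeLines(c(hdr, lines[ord]), path)
  invisible(path)
}
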