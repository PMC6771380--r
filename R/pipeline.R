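#' Configure a coverage-analysis run
#'
#' Collects every tunable of the pipeline in one object, so that a run can be
#' reproduced from its echoed configuration alone.
#'
#' @param counts_dir Directory of per-sample window count TSVs (see
#'   [write_counts_tsv()]); ignored when `samples` is given.
#' @param samples A list of `gbs_counts` tibbles (programmatic input).
#' @param out_dir Output directory (created if missing).
#' @param window_size Window width in bp (recorded for provenance; counts
#'   carry their own grid).
#' @param min_mapq,min_aligned Read filter settings (recorded; applied when
#'   counting from alignments).
#' @param reference `"median"` or `"ancestor"`.
#' @param ancestor_id Ancestor sample id for `reference = "ancestor"`.
#' @param k Rolling-mean width (odd).
#' @param prob Outlier probability threshold.
#' @param sidedness `"two_sided"` or `"upper"`.
#' @param min_outliers Minimum flagged windows per stretch.
#' @param long_min_outliers Flagged-window count defining "long" stretches
#'   (default 30, at least 15 Mb at 500-kb windows).
#' @param min_reads Minimum passing reads to keep a sample (default 100,000).
#' @param frequency_threshold Fraction of samples defining robust windows.
#' @param seed Seed applied before any stochastic step (`NA` for none).
#' @return A list of class `run_config`.
#' @export
run_config <- function(counts_dir = NULL, samples = NULL, out_dir = ".",
                       window_size = 500000, min_mapq = 20, min_aligned = 30,
                       reference = "median", ancestor_id = NULL, k = 5,
                       prob = 0.9999, sidedness = "two_sided",
                       min_outliers = 3, long_min_outliers = 30,
                       min_reads = 100000, frequency_threshold = 0.03,
                       seed = NA) {
  cfg <- list(counts_dir = counts_dir, samples = samples, out_dir = out_dir,
              window_size = window_size, min_mapq = min_mapq,
              min_aligned = min_aligned, reference = reference,
              ancestor_id = ancestor_id, k = k, prob = prob,
              sidedness = sidedness, min_outliers = min_outliers,
              long_min_outliers = long_min_outliers, min_reads = min_reads,
              frequency_threshold = frequency_threshold, seed = seed)
  stopifnot(cfg$reference %in% c("median", "ancestor"),
            cfg$prob > 0, cfg$prob < 1, cfg$min_outliers >= 1,
            cfg$long_min_outliers >= 1, cfg$min_reads >= 0)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' YAML keys mirror the arguments of [run_config()]; explicitly supplied
#' arguments override the file.
#'
#' @param path YAML file.
#' @param ... Overrides passed on to [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  file_cfg <- yaml::read_yaml(path)
  over <- list(...)
  file_cfg[names(over)] <- over
  do.call(run_config, file_cfg)
}

#' Run the full GBS coverage-analysis pipeline
#'
#' Loads (or takes) per-sample window counts, discards low-coverage samples,
#' builds denoised log2-ratio profiles against the configured reference,
#' flags outlier windows, assembles gap-tolerant stretches (all and "long"),
#' summarises outlier frequency across the collection, and writes every
#' result plus a configuration echo to the output directory.
#'
#' Written files: `profiles.tsv`, `stretches.bed` + `stretches.tsv`,
#' `long_stretches.tsv` (per-sample report with the largest stretch rendered
#' in Mb and its type Low/High), `frequency.tsv`, `discarded.tsv`,
#' `config.yaml` and `log.txt`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `windows`, `kept`, `discarded`, `profiles`,
#'   `calls`, `stretches`, `long_stretches`, `longest`, `frequency` and
#'   `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.na(config$seed) && !is.null(config$seed)) set.seed(config$seed)
  log_lines <- character(0)
  say <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }

  samples <- config$samples
  if (is.null(samples)) {
    if (is.null(config$counts_dir)) {
      stop("run_pipeline: either samples or counts_dir must be given",
           call. = FALSE)
    }
    files <- sort(list.files(config$counts_dir, pattern = "\\.tsv$",
                             full.names = TRUE))
    if (length(files) == 0) {
      stop("run_pipeline: no count tables found in ", config$counts_dir,
           call. = FALSE)
    }
    samples <- lapply(files, read_counts_tsv)
  }
  if (length(samples) == 0) stop("run_pipeline: no samples", call. = FALSE)
  say("samples loaded: ", length(samples))

  qc <- qc_samples(samples, min_reads = config$min_reads)
  say("samples kept: ", length(qc$kept), "; discarded (< ", config$min_reads,
      " passing reads): ", length(qc$discarded))
  if (length(qc$kept) == 0) {
    stop("run_pipeline: all samples discarded by the read-count filter",
         call. = FALSE)
  }

  # rebuild the grid from the first sample's coordinates
  first <- qc$kept[[1]]
  lens <- tapply(first$end, as.character(first$chrom), max)
  lens <- lens[as.character(unique(first$chrom))]
  windows <- build_windows(stats::setNames(as.numeric(lens), names(lens)),
                           window_size = attr(first, "window_size") %||%
                             max(first$end - first$start))

  profiles <- coverage_profiles(qc$kept, windows,
                                reference = config$reference,
                                ancestor_id = config$ancestor_id,
                                k = config$k)
  calls <- call_outliers(profiles, prob = config$prob,
                         sidedness = config$sidedness)
  stretches <- find_stretches(calls, min_outliers = config$min_outliers)
  long_stretches <- find_stretches(calls,
                                   min_outliers = config$long_min_outliers)
  longest <- longest_stretch(stretches)
  freq <- frequency_summary(calls,
                            threshold_fraction = config$frequency_threshold)
  say("flagged windows: ", sum(calls$flag),
      "; stretches: ", nrow(stretches),
      "; long stretches (>= ", config$long_min_outliers, " outliers): ",
      nrow(long_stretches))

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  write_profile_tsv(profiles, out("profiles.tsv"))
  write_stretches_bed(stretches, out("stretches.bed"))
  readr::write_tsv(dplyr::mutate(tibble::as_tibble(stretches),
                                 chrom = as.character(.data$chrom)),
                   out("stretches.tsv"))
  readr::write_tsv(stretch_report(long_stretches, qc$kept),
                   out("long_stretches.tsv"))
  readr::write_tsv(dplyr::mutate(tibble::as_tibble(freq),
                                 chrom = as.character(.data$chrom)),
                   out("frequency.tsv"))
  readr::write_tsv(sample_totals(qc$discarded), out("discarded.tsv"))
  cfg_echo <- config[setdiff(names(config), "samples")]
  cfg_echo$n_samples_input <- length(samples)
  yaml::write_yaml(lapply(cfg_echo, function(x) if (is.null(x)) NA else x),
                   out("config.yaml"))
  writeLines(log_lines, out("log.txt"))

  invisible(list(windows = windows, kept = qc$kept, discarded = qc$discarded,
                 profiles = profiles, calls = calls, stretches = stretches,
                 long_stretches = long_stretches, longest = longest,
                 frequency = freq,
                 files = vapply(c("profiles.tsv", "stretches.bed",
                                  "stretches.tsv", "long_stretches.tsv",
                                  "frequency.tsv", "discarded.tsv",
                                  "config.yaml", "log.txt"),
                                out, character(1))))
}

#' Per-sample report of large coverage modifications
#'
#' One row per sample carrying at least one stretch: the sample id, its
#' passing-read total, the largest stretch rendered in Mb, and the type
#' (`Low` for decreased, `High` for increased coverage).
#'
#' @param stretches A `gbs_stretches` tibble (typically long stretches only).
#' @param samples The list of `gbs_counts` the stretches came from.
#' @return A tibble with columns `sample_id`, `total_passing`,
#'   `largest_stretch`, `n_outliers`, `type`.
#' @export
stretch_report <- function(stretches, samples) {
  totals <- sample_totals(samples)
  top <- longest_stretch(stretches)
  if (nrow(top) == 0) {
    return(tibble::tibble(sample_id = character(), total_passing = integer(),
                          largest_stretch = character(),
                          n_outliers = integer(), type = character()))
  }
  top |>
    dplyr::left_join(totals, by = "sample_id") |>
    dplyr::transmute(.data$sample_id, .data$total_passing,
                     largest_stretch = format_region_mb(.data$chrom,
                                                        .data$start,
                                                        .data$end),
                     .data$n_outliers,
                     type = dplyr::if_else(.data$direction == "increased",
                                           "High", "Low"))
}
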