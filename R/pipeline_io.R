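#' Pipeline run configuration
#'
#' Defaults follow the reference analysis: 20-TR windows with 50% overlap,
#' structural resolution `gamma = 1`, ordinal temporal coupling
#' `omega = 0.4` (robustness variant 1), 100 optimizer runs per subject,
#' network-level FDR threshold `q < 0.05`, ROI-level exploratory threshold
#' `p < 0.001`, age bins 7/12/18/25, and diagnosis-only harmonization.
#'
#' @param window_length,window_step sliding-window length and step (TR).
#' @param gamma,omega,n_runs multilayer-modularity parameters; see
#'   [modularity_params()].
#' @param seed master seed for the whole run.
#' @param q_threshold network-level FDR threshold.
#' @param roi_p_threshold uncorrected ROI-level threshold.
#' @param age_bins break points of the age strata.
#' @param harmonize_age retain age as a protected covariate in
#'   harmonization (robustness variant); default diagnosis only.
#' @param welch use Welch rather than pooled-variance t-tests.
#' @return object of class `run_config` (a named list that round-trips
#'   through [save_config()] / [load_config()] unchanged).
#' @export
run_config <- function(window_length = 20L, window_step = 10L,
                       gamma = 1, omega = 0.4, n_runs = 100L, seed = 1L,
                       q_threshold = 0.05, roi_p_threshold = 0.001,
                       age_bins = c(7, 12, 18, 25),
                       harmonize_age = FALSE, welch = FALSE) {
  cfg <- list(window_length = as.integer(window_length),
              window_step = as.integer(window_step),
              gamma = as.numeric(gamma), omega = as.numeric(omega),
              n_runs = as.integer(n_runs), seed = as.integer(seed),
              q_threshold = as.numeric(q_threshold),
              roi_p_threshold = as.numeric(roi_p_threshold),
              age_bins = as.numeric(age_bins),
              harmonize_age = isTRUE(harmonize_age),
              welch = isTRUE(welch))
  class(cfg) <- "run_config"
  cfg
}

#' Save / load a run configuration (JSON)
#' @param config a [run_config()].
#' @param path file path.
#' @return [load_config()] returns a [run_config()] identical to the one
#'   saved.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

#' Read / write ROI time series
#'
#' Tab-delimited text: header row of node ids, one row per timepoint.
#' When a partition is given the columns are checked against its analysis
#' set and returned in partition order.
#' @param path file path.
#' @param partition optional [node_partition()] to validate against.
#' @return numeric T x K matrix with node-id column names.
#' @export
read_timeseries <- function(path, partition = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "numeric")
  ids <- colnames(tab)
  if (anyDuplicated(ids))
    stop("duplicate node ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(tab)
  if (anyNA(m)) stop("non-numeric or missing cells in ", path)
  if (!is.null(partition)) {
    want <- analysis_nodes(partition)
    extra <- setdiff(ids, want)
    missing <- setdiff(want, ids)
    if (length(extra) || length(missing))
      stop("node set mismatch in ", path,
           if (length(missing)) paste0("; missing: ",
                                       paste(missing, collapse = ", ")),
           if (length(extra)) paste0("; unknown: ",
                                     paste(extra, collapse = ", ")))
    m <- m[, want, drop = FALSE]
  }
  m
}

#' @rdname read_timeseries
#' @param ts T x K matrix with node-id column names.
#' @export
write_timeseries <- function(ts, path) {
  utils::write.table(format(ts, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Analyze one subject's time series
#'
#' construct -> detect -> metrics for a single subject: sliding-window
#' connectivity, consensus allegiance over `n_runs` optimizer repetitions,
#' then network-level recruitment and pairwise integration.
#' @param ts T x K time-series matrix (columns = analysis nodes).
#' @param part a [node_partition()].
#' @param config a [run_config()].
#' @param seed subject-specific seed (derive from the master seed).
#' @param subject_id identifier for the metric rows.
#' @return list with `allegiance` and tidy `metrics`.
#' @export
analyze_subject <- function(ts, part, config = run_config(),
                            seed = config$seed, subject_id = "s1") {
  scheme <- make_windows(nrow(ts), config$window_length, config$window_step)
  net <- window_connectivity(ts, scheme)
  params <- modularity_params(gamma = config$gamma, omega = config$omega,
                              n_runs = config$n_runs, seed = seed)
  alleg <- consensus_allegiance(net, params)
  list(allegiance = alleg,
       metrics = subject_metrics(alleg, part, subject_id))
}

#' Run the full pipeline on a cohort directory
#'
#' Orchestrates construct -> detect -> metrics -> harmonize -> compare on a
#' cohort laid out as written by [write_cohort()]: per-subject `<id>.tsv`
#' time series, `metadata.tsv` (subject_id, group, site, age) and
#' `partition.tsv`.  Writes the tidy metric table (raw and harmonized),
#' network-level test results, ROI-level follow-up, age-stratified results
#' and a JSON manifest (config snapshot, seeds, output checksums) to
#' `out_dir`.  Deterministic: the same cohort, configuration and master
#' seed reproduce every output byte-identically.
#'
#' @param config a [run_config()].
#' @param cohort_dir input directory.
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @return list with `metrics`, `metrics_harmonized` (wide matrices),
#'   `results`, `roi_results`, `age_results`, `allegiances`, `meta`,
#'   `config`, invisibly.
#' @export
run_pipeline <- function(config, cohort_dir, out_dir = NULL) {
  part <- read_partition(file.path(cohort_dir, "partition.tsv"))
  meta <- utils::read.delim(file.path(cohort_dir, "metadata.tsv"),
                            stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "site", "age")
  if (!all(need %in% names(meta)))
    stop("metadata.tsv must have columns ", paste(need, collapse = ", "))

  allegiances <- list()
  metrics <- list()
  for (i in seq_len(nrow(meta))) {
    sid <- meta$subject_id[i]
    f <- file.path(cohort_dir, paste0(sid, ".tsv"))
    if (!file.exists(f)) stop("stage construct: missing time series ", f)
    ts <- read_timeseries(f, part)
    res <- analyze_subject(ts, part, config,
                           seed = subject_seed(config$seed, i),
                           subject_id = sid)
    allegiances[[sid]] <- res$allegiance
    metrics[[sid]] <- res$metrics
  }
  tidy <- do.call(rbind, metrics)
  wide <- metrics_wide(tidy)
  wide <- wide[, meta$subject_id, drop = FALSE]

  design <- batch_design(meta$site, meta$group,
                         age = meta$age, retain_age = config$harmonize_age)
  harmonized <- if (nlevels(design$batch) > 1)
    combat_adjust(wide, design) else wide
  attr(harmonized, "combat") <- NULL

  results <- network_level_comparison(harmonized, meta$group,
                                      q_threshold = config$q_threshold,
                                      welch = config$welch)
  roi <- roi_followup(allegiances, part, meta$group, results,
                      p_threshold = config$roi_p_threshold,
                      welch = config$welch)
  age_results <- tryCatch(
    suppressWarnings(
      age_stratified_comparison(harmonized, meta$group, meta$age,
                                bins = config$age_bins,
                                q_threshold = config$q_threshold,
                                welch = config$welch)),
    error = function(e) list())

  out <- list(metrics = wide, metrics_harmonized = harmonized,
              results = results, roi_results = roi,
              age_results = age_results, allegiances = allegiances,
              meta = meta, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  invisible(out)
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) {
    utils::write.table(x, file.path(out_dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f
  }
  files <- c(
    wt(metrics_tidy(out$metrics), "metrics.tsv"),
    wt(metrics_tidy(out$metrics_harmonized), "metrics_harmonized.tsv"),
    wt(out$results, "results.tsv"),
    wt(out$roi_results, "roi_results.tsv"))
  for (bin in names(out$age_results)) {
    f <- paste0("results_age_", gsub("[^0-9]+", "_", bin), ".tsv")
    files <- c(files, wt(out$age_results[[bin]], f))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("dynrecon")),
    config = unclass(out$config),
    n_subjects = nrow(out$meta),
    seeds = vapply(seq_len(nrow(out$meta)),
                   function(i) subject_seed(out$config$seed, i), 1L),
    checksums = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$checksums) <- files
  # written last, atomically: a complete manifest marks a complete run
  tmp <- file.path(out_dir, ".manifest.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA)
  file.rename(tmp, file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}
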