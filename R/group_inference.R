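#' Independent two-sample t-test
#'
#' Pooled-variance (Student) two-sided t-test by default; `welch = TRUE`
#' switches to the Welch unequal-variance form.  Called as
#' `two_sample_t(case, control)`, `t < 0` means the case mean is below the
#' control mean.
#'
#' @param x,y numeric samples, each of length >= 2 with finite variance.
#' @param welch logical; use Welch's approximation.
#' @return list with `t`, `p`, `df`.
#' @export
two_sample_t <- function(x, y, welch = FALSE) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each sample needs at least 2 observations")
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  if (welch) {
    se2 <- vx / nx + vy / ny
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    t <- (mx - my) / sqrt(se2)
  } else {
    df <- nx + ny - 2
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / df
    t <- (mx - my) / sqrt(sp2 * (1 / nx + 1 / ny))
  }
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' Benjamini-Hochberg step-up FDR correction
#'
#' `q_(i) = min_{j >= i} m * p_(j) / j` (capped at 1); a hypothesis is
#' rejected iff its q-value does not exceed the threshold (the standard
#' step-up rule: `p_(j) <= j/m * alpha` is equivalent to `q <= alpha`).
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param q_threshold rejection threshold on the q-value (default 0.05).
#' @return list with `q` (same order as `pvals`) and `reject` (logical).
#' @export
bh_fdr <- function(pvals, q_threshold = 0.05) {
  if (length(pvals) == 0)
    return(list(q = numeric(0), reject = logical(0)))
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  m <- length(pvals)
  ord <- order(pvals)
  q_sorted <- pmin(1, cummin(rev(m * pvals[ord] / seq_len(m))))
  q <- numeric(m)
  q[ord] <- rev(q_sorted)
  list(q = q, reject = q <= q_threshold)
}

#' Network-level case vs control comparison
#'
#' One independent-sample t-test per network-level parameter (9 recruitment
#' + 36 pairwise integration coefficients for a 9-network partition), with
#' Benjamini-Hochberg FDR correction applied jointly across the whole
#' family (`q < 0.05` by default).
#'
#' @param wide feature x subject matrix ([metrics_wide()]), typically
#'   harmonized.
#' @param labels `case` / `control` label per subject (matching columns).
#' @param q_threshold FDR threshold.
#' @param welch use Welch's t-test instead of pooled variance.
#' @return data.frame of TestResults: `metric_type`, `network_1`,
#'   `network_2`, `t`, `p`, `q`, `reject`, `mean_case`, `mean_control`,
#'   `n_case`, `n_control`.
#' @export
network_level_comparison <- function(wide, labels, q_threshold = 0.05,
                                     welch = FALSE) {
  labels <- as.character(labels)
  if (ncol(wide) != length(labels))
    stop("one label per subject column required")
  if (!all(c("case", "control") %in% labels))
    stop("both groups must be present")
  case <- wide[, labels == "case", drop = FALSE]
  ctrl <- wide[, labels == "control", drop = FALSE]
  parts <- strsplit(rownames(wide), "[:|]")
  res <- data.frame(
    metric_type = vapply(parts, `[`, "", 1),
    network_1 = vapply(parts, `[`, "", 2),
    network_2 = vapply(parts, function(p) if (length(p) > 2) p[3] else "", ""),
    t = NA_real_, p = NA_real_, q = NA_real_, reject = NA,
    mean_case = rowMeans(case), mean_control = rowMeans(ctrl),
    n_case = ncol(case), n_control = ncol(ctrl),
    row.names = NULL, stringsAsFactors = FALSE)
  for (f in seq_len(nrow(wide))) {
    tt <- two_sample_t(case[f, ], ctrl[f, ], welch = welch)
    res$t[f] <- tt$t
    res$p[f] <- tt$p
  }
  fdr <- bh_fdr(res$p, q_threshold)
  res$q <- fdr$q
  res$reject <- fdr$reject
  res
}

#' ROI-level follow-up of significant network results
#'
#' For each FDR-significant network-level parameter, per-node t-tests on
#' the corresponding ROI-level quantity (node recruitment for a significant
#' network recruitment; node-level cross-network allegiance for a
#' significant pair integration), reported at an uncorrected threshold
#' (`p < 0.001` by default) -- an exploratory localization step, not a
#' corrected inference.
#'
#' @param allegiances named list of per-subject [allegiance_matrix()]
#'   objects (names = subject ids, matching `labels`).
#' @param part a [node_partition()].
#' @param labels `case` / `control` per subject.
#' @param results TestResult data.frame from [network_level_comparison()].
#' @param p_threshold uncorrected p-value threshold.
#' @param welch use Welch's t-test.
#' @return data.frame with `metric_type`, `network_1`, `network_2`,
#'   `node_id`, `t`, `p`, `flagged`; zero rows when nothing is significant.
#' @export
roi_followup <- function(allegiances, part, labels, results,
                         p_threshold = 0.001, welch = FALSE) {
  sig <- results[results$reject, , drop = FALSE]
  empty <- data.frame(metric_type = character(), network_1 = character(),
                      network_2 = character(), node_id = character(),
                      t = numeric(), p = numeric(), flagged = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(sig) == 0) return(empty)
  labels <- as.character(labels)
  out <- list()
  for (k in seq_len(nrow(sig))) {
    if (sig$metric_type[k] == "recruitment") {
      vals <- vapply(allegiances, function(a)
        node_recruitment(a, part), numeric(length(analysis_nodes(part))))
      net <- network_of(part)
      vals <- vals[names(net)[net == sig$network_1[k]], , drop = FALSE]
    } else {
      vals <- vapply(allegiances, function(a)
        node_pair_integration(a, part, sig$network_1[k], sig$network_2[k]),
        node_pair_integration(allegiances[[1]], part,
                              sig$network_1[k], sig$network_2[k]))
    }
    for (node in rownames(vals)) {
      tt <- two_sample_t(vals[node, labels == "case"],
                         vals[node, labels == "control"], welch = welch)
      out[[length(out) + 1]] <- data.frame(
        metric_type = sig$metric_type[k], network_1 = sig$network_1[k],
        network_2 = sig$network_2[k], node_id = node,
        t = tt$t, p = tt$p, flagged = tt$p < p_threshold,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(list(empty), out))
}

#' Age-stratified network-level comparison
#'
#' Runs [network_level_comparison()] independently inside each age bin.
#' Default bins: primary-school `[7, 12)`, adolescent `[12, 18)`, young
#' adult `[18, 25]`.  Bins with fewer than 2 subjects in either group are
#' skipped with a warning (mirroring sparsely populated youngest bins in
#' real cohorts); if no bin is satisfiable, an error is raised.
#'
#' @inheritParams network_level_comparison
#' @param ages numeric age per subject.
#' @param bins increasing break points `c(b1, ..., bk)` defining the bins
#'   `[b1, b2), ..., [b_{k-1}, b_k]`.
#' @return named list of TestResult data.frames, one per retained bin.
#' @export
age_stratified_comparison <- function(wide, labels, ages,
                                      bins = c(7, 12, 18, 25),
                                      q_threshold = 0.05, welch = FALSE) {
  stopifnot(length(ages) == ncol(wide), !is.unsorted(bins))
  labels <- as.character(labels)
  out <- list()
  for (b in seq_len(length(bins) - 1)) {
    lo <- bins[b]; hi <- bins[b + 1]
    last <- b == length(bins) - 1
    inbin <- ages >= lo & (if (last) ages <= hi else ages < hi)
    name <- sprintf("[%g,%g%s", lo, hi, if (last) "]" else ")")
    n_case <- sum(inbin & labels == "case")
    n_ctrl <- sum(inbin & labels == "control")
    if (n_case < 2 || n_ctrl < 2) {
      warning("age bin ", name, " skipped (", n_case, " case / ", n_ctrl,
              " control subjects)")
      next
    }
    out[[name]] <- network_level_comparison(wide[, inbin, drop = FALSE],
                                            labels[inbin], q_threshold,
                                            welch)
  }
  if (length(out) == 0) stop("no age bin has >= 2 subjects per group")
  out
}

#' Independent-cohort replication
#'
#' Re-tests, in an independently analyzed cohort B, only those parameters
#' that were FDR-significant in cohort A (both cohorts must have been
#' analyzed with the same configuration), reporting for each whether the
#' group-difference sign agrees and whether it remains significant under
#' BH-FDR across the replicated subset.
#'
#' @param results_a TestResult data.frame from cohort A.
#' @param wide_b,labels_b cohort B metric matrix and group labels.
#' @param config_a,config_b the [run_config()] objects used for the two
#'   analyses; analysis-relevant fields must match.
#' @param q_threshold FDR threshold within the replicated subset.
#' @param welch use Welch's t-test.
#' @return data.frame with the replicated parameters, cohort-B `t`, `p`,
#'   `q`, `sign_agrees`, `replicated`; zero rows if A had no significant
#'   results.
#' @export
replication_run <- function(results_a, wide_b, labels_b,
                            config_a = NULL, config_b = NULL,
                            q_threshold = 0.05, welch = FALSE) {
  if (!is.null(config_a) || !is.null(config_b)) {
    keys <- c("window_length", "window_step", "gamma", "omega", "n_runs",
              "q_threshold", "roi_p_threshold", "harmonize_age", "welch")
    a <- config_a[keys]; b <- config_b[keys]
    if (!identical(a, b))
      stop("invalid replication: configurations differ in ",
           paste(keys[!mapply(identical, a, b)], collapse = ", "))
  }
  sig <- results_a[results_a$reject, , drop = FALSE]
  if (nrow(sig) == 0)
    return(data.frame(metric_type = character(), network_1 = character(),
                      network_2 = character(), t_a = numeric(),
                      t = numeric(), p = numeric(), q = numeric(),
                      sign_agrees = logical(), replicated = logical(),
                      stringsAsFactors = FALSE))
  res_b <- network_level_comparison(wide_b, labels_b,
                                    q_threshold = q_threshold, welch = welch)
  key <- function(d) paste(d$metric_type, d$network_1, d$network_2)
  idx <- match(key(sig), key(res_b))
  if (anyNA(idx))
    stop("cohort B is missing replicated parameter(s): ",
         paste(key(sig)[is.na(idx)], collapse = ", "))
  sub <- res_b[idx, , drop = FALSE]
  fdr <- bh_fdr(sub$p, q_threshold)           # FDR within replicated subset
  data.frame(metric_type = sub$metric_type, network_1 = sub$network_1,
             network_2 = sub$network_2, t_a = sig$t,
             t = sub$t, p = sub$p, q = fdr$q,
             sign_agrees = sign(sub$t) == sign(sig$t),
             replicated = fdr$reject & sign(sub$t) == sign(sig$t),
             row.names = NULL, stringsAsFactors = FALSE)
}
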