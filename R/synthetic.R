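#' Specify a synthetic multi-site two-group cohort
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: piecewise-stationary ROI time series in which nodes of the same
#' latent community share a common signal, with group-dependent probabilities
#' that a node temporarily detaches from its home network, additive +
#' multiplicative site effects, and Gaussian observation noise.
#'
#' Within each latent state (a block of `state_length` timepoints) every node
#' belongs to one community.  Its home community is its functional network;
#' with probability `p_detach[group, network]` it instead joins one uniformly
#' chosen foreign network's community for that whole state.  Nodes in the
#' same community share a latent signal so that their correlation is
#' `rho_in` before observation noise (noise attenuates the realized
#' correlation to roughly `rho_in / (1 + noise_sd^2)` at unit site scale).
#'
#' Site effects are per-node affine perturbations (mean shift, variance
#' scaling) of the observed signal.  Pearson correlation is invariant to
#' per-node affine maps, so these effects leave the planted community
#' structure intact by design; they model the batch structure that
#' harmonization of derived metrics is meant to remove.
#'
#' @param n_per_group subjects per diagnostic group (case, control); >= 2.
#' @param n_sites number of acquisition sites.
#' @param n_timepoints timepoints per subject (`T`); must be an exact
#'   multiple of `state_length` with at least 2 states.
#' @param partition a [node_partition()]; default [toy_partition()] with 5
#'   nodes per network (45 analysis nodes).
#' @param state_length timepoints per latent community state.
#' @param rho_in within-community signal correlation in `[0, 1]`.
#' @param p_detach 2 x n_networks numeric matrix (rows `case`, `control`,
#'   columns = network labels) of per-state detachment probabilities; see
#'   [planted_detach()].
#' @param site_shift,site_scale numeric vectors (length `n_sites`) of
#'   additive offsets and multiplicative scalings applied per site.
#' @param noise_sd standard deviation of i.i.d. Gaussian observation noise.
#' @param age_range list with elements `case`, `control`, each `c(lo, hi)`
#'   in years; ages are drawn uniformly.
#' @param seed integer master seed; generation is bit-reproducible.
#' @return an object of class `cohort_spec` (a validated list).
#' @export
cohort_spec <- function(n_per_group = 30,
                        n_sites = 2,
                        n_timepoints = 200,
                        partition = toy_partition(5),
                        state_length = 40,
                        rho_in = 0.8,
                        p_detach = planted_detach(partition),
                        site_shift = 0.3 * (seq_len(n_sites) - 1),
                        site_scale = 1 + 0.15 * (seq_len(n_sites) - 1),
                        noise_sd = 0.3,
                        age_range = list(case = c(7, 25), control = c(7, 25)),
                        seed = 1L) {
  stopifnot(inherits(partition, "node_partition"))
  if (n_per_group < 2)
    stop("n_per_group must be >= 2 (group inference impossible otherwise)")
  if (rho_in < 0 || rho_in > 1) stop("rho_in must be in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  n_states <- n_timepoints / state_length
  if (n_states != round(n_states) || n_states < 2)
    stop("n_timepoints must divide into >= 2 equal states of state_length")
  nets <- names(network_sizes(partition))
  if (!is.matrix(p_detach) ||
      !setequal(rownames(p_detach), c("case", "control")) ||
      !setequal(colnames(p_detach), nets))
    stop("p_detach must be a matrix with rows case/control and one column ",
         "per network")
  p_detach <- p_detach[c("case", "control"), nets, drop = FALSE]
  if (any(p_detach < 0 | p_detach > 1)) stop("p_detach must be in [0, 1]")
  stopifnot(length(site_shift) == n_sites, length(site_scale) == n_sites)
  spec <- list(n_per_group = as.integer(n_per_group),
               n_sites = as.integer(n_sites),
               n_timepoints = as.integer(n_timepoints),
               partition = partition,
               state_length = as.integer(state_length),
               rho_in = rho_in, p_detach = p_detach,
               site_shift = site_shift, site_scale = site_scale,
               noise_sd = noise_sd, age_range = age_range,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  spec
}

#' Detachment-probability matrix with an optional planted group effect
#'
#' Baseline detachment probability for every (group, network) cell, with the
#' case group's probability raised in one designated network.  The default
#' effect (case 0.4 vs control 0.1 in the DMN-like network) is the
#' generator's reference effect size for power analyses; `case_p = baseline`
#' gives a null configuration.
#'
#' @param partition a [node_partition()].
#' @param baseline detachment probability for all cells.
#' @param effect_network network receiving the planted case effect, or
#'   `NULL` for a null (no-effect) matrix.
#' @param case_p case-group probability in `effect_network`.
#' @return 2 x n_networks matrix, rows `case`, `control`.
#' @export
planted_detach <- function(partition, baseline = 0.1,
                           effect_network = NULL, case_p = 0.4) {
  nets <- names(network_sizes(partition))
  m <- matrix(baseline, 2, length(nets),
              dimnames = list(c("case", "control"), nets))
  if (!is.null(effect_network)) {
    if (!effect_network %in% nets) stop("unknown network: ", effect_network)
    m["case", effect_network] <- case_p
  }
  m
}

# deterministic per-subject sub-seed below 2^31
subject_seed <- function(master, idx) {
  as.integer((as.numeric(master) * 7919 + as.numeric(idx) * 104729) %%
               2147483647)
}

#' Generate one subject's time series with ground truth
#'
#' @param spec a [cohort_spec()].
#' @param group `"case"` or `"control"`.
#' @param site site index in `1:n_sites`.
#' @param seed integer seed for this subject's random stream.
#' @param subject_id identifier stored in the record.
#' @param age age in years (drawn by [generate_cohort()]).
#' @return list with elements `record` (class `subject_record`: subject_id,
#'   group, site, age, `timeseries` T x K matrix with node-id column names)
#'   and `truth` (class `ground_truth`: per-state community label per node,
#'   detachment flags, state boundaries).
#' @export
generate_subject <- function(spec, group = c("case", "control"), site = 1L,
                             seed = 1L, subject_id = "s1", age = NA_real_) {
  group <- match.arg(group)
  stopifnot(inherits(spec, "cohort_spec"), site >= 1, site <= spec$n_sites)
  part <- spec$partition
  nodes <- analysis_nodes(part)
  net <- network_of(part)
  nets <- names(network_sizes(part))
  K <- length(nodes)
  S <- spec$n_timepoints %/% spec$state_length
  Ls <- spec$state_length

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  net_idx <- match(net[nodes], nets)          # home community per node
  assignment <- matrix(0L, S, K)              # community label per state/node
  detached <- matrix(FALSE, S, K)
  for (s in seq_len(S)) {
    comm <- net_idx
    pd <- spec$p_detach[group, net[nodes]]
    leave <- stats::runif(K) < pd
    if (any(leave)) {
      for (i in which(leave)) {
        foreign <- setdiff(seq_along(nets), net_idx[i])
        comm[i] <- foreign[sample.int(length(foreign), 1L)]
      }
    }
    assignment[s, ] <- comm
    detached[s, ] <- leave
  }

  r <- sqrt(spec$rho_in)
  ts <- matrix(0, spec$n_timepoints, K)
  for (s in seq_len(S)) {
    rows <- ((s - 1) * Ls + 1):(s * Ls)
    z <- matrix(stats::rnorm(Ls * length(nets)), Ls, length(nets))
    e <- matrix(stats::rnorm(Ls * K), Ls, K)
    ts[rows, ] <- r * z[, assignment[s, ], drop = FALSE] +
      sqrt(1 - spec$rho_in) * e
  }
  ts <- spec$site_shift[site] + spec$site_scale[site] * ts
  if (spec$noise_sd > 0)
    ts <- ts + spec$noise_sd *
      matrix(stats::rnorm(length(ts)), nrow(ts), ncol(ts))
  colnames(ts) <- nodes

  record <- structure(list(subject_id = subject_id, group = group,
                           site = as.integer(site), age = age,
                           timeseries = ts),
                      class = "subject_record")
  truth <- structure(list(subject_id = subject_id, n_states = S,
                          state_length = Ls, communities = nets,
                          assignment = assignment, detached = detached),
                     class = "ground_truth")
  list(record = record, truth = truth)
}

#' Generate a full cohort
#'
#' Subjects are generated per group with sites assigned round-robin, so site
#' composition is balanced across groups.  Ages are uniform within the
#' group's configured range.  Each subject uses a deterministic sub-seed of
#' `spec$seed`, so the cohort is bit-reproducible and independent of
#' generation order.
#'
#' @param spec a [cohort_spec()].
#' @return list with `records` (list of `subject_record`) and `truths`
#'   (list of `ground_truth`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- rep(c("case", "control"), each = spec$n_per_group)
  sites <- rep_len(seq_len(spec$n_sites), spec$n_per_group)
  sites <- c(sites, sites)                     # same balance in both groups
  n <- length(groups)
  ids <- sprintf("sub%03d", seq_len(n))

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(subject_seed(spec$seed, 0L))
  ages <- numeric(n)
  for (g in c("case", "control")) {
    rng <- spec$age_range[[g]]
    ages[groups == g] <- stats::runif(spec$n_per_group, rng[1], rng[2])
  }

  records <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    out <- generate_subject(spec, groups[i], sites[i],
                            seed = subject_seed(spec$seed, i),
                            subject_id = ids[i], age = ages[i])
    records[[i]] <- out$record
    truths[[i]] <- out$truth
  }
  list(records = records, truths = truths)
}

#' Ground-truth co-assignment frequencies
#'
#' Fraction of latent states in which two nodes share a community --- the
#' noiseless analogue of the allegiance matrix, computed directly from the
#' generator's ground truth.
#' @param truth a `ground_truth` object.
#' @return K x K symmetric matrix with unit diagonal.
#' @export
gt_coassignment <- function(truth) {
  A <- truth$assignment
  S <- nrow(A)
  K <- ncol(A)
  P <- matrix(0, K, K)
  for (s in seq_len(S)) {
    same <- outer(A[s, ], A[s, ], "==")
    P <- P + same
  }
  P / S
}

#' Cohort metadata as a data.frame
#' @param records list of `subject_record`.
#' @return data.frame with subject_id, group, site, age.
#' @export
cohort_metadata <- function(records) {
  data.frame(subject_id = vapply(records, `[[`, "", "subject_id"),
             group = vapply(records, `[[`, "", "group"),
             site = vapply(records, function(r) r$site, 1L),
             age = vapply(records, function(r) as.numeric(r$age), 1.0),
             stringsAsFactors = FALSE)
}

#' Write a cohort to disk
#'
#' One tab-delimited time-series file per subject (header = node ids, one
#' row per timepoint), a `metadata.tsv` table, the partition table, and a
#' `ground_truth.json` sidecar.
#' @param cohort result of [generate_cohort()].
#' @param spec the [cohort_spec()] used.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort$records)
    write_timeseries(rec$timeseries,
                     file.path(dir, paste0(rec$subject_id, ".tsv")))
  utils::write.table(cohort_metadata(cohort$records),
                     file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_partition(spec$partition, file.path(dir, "partition.tsv"))
  gt <- lapply(cohort$truths, function(tr)
    list(subject_id = tr$subject_id, n_states = tr$n_states,
         state_length = tr$state_length, communities = tr$communities,
         assignment = tr$assignment))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
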