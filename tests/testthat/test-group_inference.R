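test_that("pooled t-test matches hand computation and stats::t.test", {
  r <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3.674, tolerance = 1e-3)
  expect_equal(r$p, 0.0214, tolerance = 1e-2)
  expect_equal(r$df, 4)

  # identical samples: t = 0, p = 1
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # scale invariance
  r10 <- two_sample_t(10 * c(1, 2, 3), 10 * c(4, 5, 6))
  expect_equal(r10$t, r$t)
  expect_equal(r10$p, r$p)

  # oracle: stats::t.test on random samples, both variants
  set.seed(101)
  for (i in 1:20) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1), mean = 0.5)
    mine <- two_sample_t(x, y)
    ref <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    mw <- two_sample_t(x, y, welch = TRUE)
    rw <- stats::t.test(x, y)
    expect_equal(mw$t, unname(rw$statistic), tolerance = 1e-12)
    expect_equal(mw$p, rw$p.value, tolerance = 1e-12)
  }

  expect_error(two_sample_t(1, c(1, 2)), "at least 2")
  # sign convention: case below control gives t < 0
  expect_lt(two_sample_t(c(0, 0.1), c(1, 1.1))$t, 0)
})

test_that("BH step-up matches the hand example and p.adjust exactly", {
  r <- bh_fdr(c(0.001, 0.01, 0.02, 0.05), 0.05)
  expect_true(all(r$reject))                     # p_(4) = 0.05 <= 0.05
  expect_equal(r$q, c(0.004, 0.02, 0.0266667, 0.05), tolerance = 1e-5)

  expect_false(any(bh_fdr(rep(1, 10), 0.05)$reject))
  one <- bh_fdr(0.04, 0.05)
  expect_equal(one$q, 0.04)
  expect_true(one$reject)
  empty <- bh_fdr(numeric(0), 0.05)
  expect_length(empty$q, 0)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(202)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p)$q, stats::p.adjust(p, "BH"), tolerance = 1e-14)
  }
})

# deterministic wide matrix with a planted DMN-recruitment group effect
fake_wide <- function(n_per_group = 20, effect = 0, sd = 0.05, seed = 1,
                      feature = "recruitment:DMN") {
  set.seed(seed)
  part <- toy_partition(2)
  feats <- rownames(metrics_wide(subject_metrics(random_allegiance(18),
                                                 part, "tmp")))
  n <- 2 * n_per_group
  wide <- matrix(rnorm(length(feats) * n, mean = 0.5, sd = sd),
                 length(feats), n,
                 dimnames = list(feats, sprintf("s%03d", 1:n)))
  labels <- rep(c("case", "control"), each = n_per_group)
  wide[feature, labels == "case"] <-
    wide[feature, labels == "case"] - effect
  list(wide = wide, labels = labels)
}

test_that("network-level comparison emits 45 jointly corrected tests", {
  f <- fake_wide(n_per_group = 15, effect = 0.2, seed = 3)
  res <- network_level_comparison(f$wide, f$labels)
  expect_equal(nrow(res), 45)
  expect_equal(sum(res$metric_type == "recruitment"), 9)
  expect_equal(sum(res$metric_type == "integration"), 36)
  expect_equal(res$reject, res$q <= 0.05)
  expect_equal(res$q, bh_fdr(res$p)$q)           # joint family of 45
  dmn <- res[res$metric_type == "recruitment" & res$network_1 == "DMN", ]
  expect_lt(dmn$t, 0)
  expect_true(dmn$reject)
  expect_equal(dmn$n_case, 15)
  expect_lt(dmn$mean_case, dmn$mean_control)

  expect_error(network_level_comparison(f$wide, rep("case", 30)),
               "both groups")
  expect_error(network_level_comparison(f$wide, f$labels[-1]),
               "one label per subject")
})

# synthetic allegiance cohort: case subjects lose within-DMN allegiance in
# a designated half of the DMN nodes
fake_allegiance_cohort <- function(n_per_group = 12, drop = 0.5,
                                   seed = 7, noise = 0.02) {
  set.seed(seed)
  part <- toy_partition(6)                      # DMN has 6 nodes
  nodes <- analysis_nodes(part)
  net <- network_of(part)
  K <- length(nodes)
  base <- matrix(0.05, K, K)
  for (N in unique(net)) {
    idx <- which(net == N)
    base[idx, idx] <- 0.9
  }
  diag(base) <- 1
  dimnames(base) <- list(nodes, nodes)
  affected <- names(net)[net == "DMN"][1:3]
  labels <- rep(c("case", "control"), each = n_per_group)
  allegs <- lapply(seq_along(labels), function(i) {
    E <- matrix(rnorm(K * K, sd = noise), K, K)
    E <- (E + t(E)) / 2
    P <- base + E
    if (labels[i] == "case") {
      dmn <- names(net)[net == "DMN"]
      P[affected, dmn] <- P[affected, dmn] - drop
      P[dmn, affected] <- t(P[affected, dmn])
    }
    diag(P) <- 1
    P <- pmin(pmax(P, 0), 1)
    P
  })
  names(allegs) <- sprintf("s%03d", seq_along(labels))
  list(allegs = allegs, labels = labels, part = part, affected = affected)
}

test_that("ROI follow-up localizes the affected nodes", {
  fc <- fake_allegiance_cohort()
  metrics <- do.call(rbind, lapply(names(fc$allegs), function(id)
    subject_metrics(fc$allegs[[id]], fc$part, id)))
  res <- network_level_comparison(metrics_wide(metrics), fc$labels)
  expect_true(res[res$metric_type == "recruitment" &
                  res$network_1 == "DMN", "reject"])

  roi <- roi_followup(fc$allegs, fc$part, fc$labels, res)
  rec <- roi[roi$metric_type == "recruitment" & roi$network_1 == "DMN", ]
  flagged <- rec$node_id[rec$flagged]
  expect_true(all(grepl("^DMN", flagged)))       # confined to DMN nodes
  expect_gte(length(intersect(flagged, fc$affected)),
             ceiling(0.7 * length(fc$affected)))

  # no significant networks -> empty result, not an error
  null_res <- res
  null_res$reject <- FALSE
  expect_equal(nrow(roi_followup(fc$allegs, fc$part, fc$labels, null_res)),
               0)
})

test_that("null ROI follow-up flags almost nothing at p < 0.001", {
  set.seed(83)
  part <- toy_partition(4)
  K <- length(analysis_nodes(part))
  labels <- rep(c("case", "control"), each = 15)
  allegs <- lapply(seq_along(labels), function(i) {
    P <- random_allegiance(K)
    dimnames(P) <- list(analysis_nodes(part), analysis_nodes(part))
    P
  })
  names(allegs) <- sprintf("s%03d", seq_along(labels))
  forced <- data.frame(metric_type = "recruitment", network_1 = "DMN",
                       network_2 = "", reject = TRUE,
                       stringsAsFactors = FALSE)
  roi <- roi_followup(allegs, part, labels, forced)
  expect_lte(sum(roi$flagged), 1)                # expected 0.004 flags
})

test_that("age stratification skips thin bins and splits correctly", {
  f <- fake_wide(n_per_group = 60, effect = 0, seed = 5)
  set.seed(6)
  ages <- runif(120, 8, 24)
  res <- age_stratified_comparison(f$wide, f$labels, ages)
  expect_length(res, 3)
  expect_true(all(vapply(res, nrow, 1L) == 45))
  expect_named(res, c("[7,12)", "[12,18)", "[18,25]"))

  # effect planted only in the adolescent stratum
  f2 <- fake_wide(n_per_group = 60, effect = 0, seed = 8)
  teen <- ages >= 12 & ages < 18
  f2$wide["recruitment:DMN", teen & f2$labels == "case"] <-
    f2$wide["recruitment:DMN", teen & f2$labels == "case"] - 0.25
  res2 <- age_stratified_comparison(f2$wide, f2$labels, ages)
  hit <- vapply(res2, function(r)
    r[r$metric_type == "recruitment" & r$network_1 == "DMN", "reject"],
    TRUE)
  expect_true(hit[["[12,18)"]])
  expect_false(hit[["[7,12)"]])
  expect_false(hit[["[18,25]"]])

  # under-filled bin skipped with warning; all-empty errors
  expect_warning(
    resw <- age_stratified_comparison(f$wide, f$labels,
                                      c(8, 8, runif(118, 13, 24))),
    "skipped")
  expect_false("[7,12)" %in% names(resw))
  expect_error(
    suppressWarnings(
      age_stratified_comparison(f$wide, f$labels, rep(30, 120))),
    "no age bin")
})

test_that("replication re-tests only cohort-A significant parameters", {
  a <- fake_wide(n_per_group = 25, effect = 0.25, seed = 12)
  res_a <- network_level_comparison(a$wide, a$labels)
  expect_true(any(res_a$reject))

  # cohort B with the same planted effect replicates
  b <- fake_wide(n_per_group = 25, effect = 0.25, seed = 13)
  rep_same <- replication_run(res_a, b$wide, b$labels)
  expect_equal(nrow(rep_same), sum(res_a$reject))
  dmn <- rep_same[rep_same$network_1 == "DMN" &
                  rep_same$metric_type == "recruitment", ]
  expect_true(dmn$sign_agrees && dmn$replicated)

  # cohort B under the null does not
  b0 <- fake_wide(n_per_group = 25, effect = 0, seed = 14)
  rep_null <- replication_run(res_a, b0$wide, b0$labels)
  expect_false(any(rep_null$replicated[rep_null$network_1 == "DMN" &
                                       rep_null$metric_type ==
                                         "recruitment"]))

  # nothing significant in A -> empty report
  null_a <- res_a
  null_a$reject <- FALSE
  expect_equal(nrow(replication_run(null_a, b$wide, b$labels)), 0)

  # configuration mismatch invalidates the replication
  expect_error(
    replication_run(res_a, b$wide, b$labels,
                    config_a = run_config(omega = 0.4),
                    config_b = run_config(omega = 1)),
    "omega")
})
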