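# simulated feature x subject matrices with known batch / group structure
sim_features <- function(n_per_site = 30, n_feat = 45, site_delta = 0,
                         group_d = 0, sd = 1, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_site
  site <- rep(c("s1", "s2"), each = n_per_site)
  group <- rep(rep(c("case", "control"), length.out = n_per_site), 2)
  dat <- matrix(rnorm(n_feat * n, sd = sd), n_feat, n)
  dat[, site == "s2"] <- dat[, site == "s2"] + site_delta
  dat[, group == "case"] <- dat[, group == "case"] + group_d
  list(dat = dat, site = site, group = group)
}

test_that("no batch effect implies near-identity adjustment", {
  rms <- vapply(c(30, 120), function(n) {
    s <- sim_features(n_per_site = n, site_delta = 0, seed = 11)
    adj <- combat_adjust(s$dat, batch_design(s$site, s$group))
    sqrt(mean((adj - s$dat)^2))
  }, 0)
  expect_lt(rms[1], 0.25)
  expect_lt(rms[2], rms[1])                      # shrinks as n grows
})

test_that("a planted additive site offset is removed", {
  delta <- 2
  s <- sim_features(n_per_site = 30, site_delta = delta, seed = 21)
  adj <- combat_adjust(s$dat, batch_design(s$site, s$group))
  before <- rowMeans(s$dat[, s$site == "s2"]) -
    rowMeans(s$dat[, s$site == "s1"])
  after <- rowMeans(adj[, s$site == "s2"]) -
    rowMeans(adj[, s$site == "s1"])
  # the planted offset (shared by all features) is removed: what remains
  # per feature is residual sampling noise partially re-exposed by EB
  # shrinkage, so the bound applies to the aggregate offset and to the
  # average reduction, not to each noisy per-feature difference
  expect_lt(abs(mean(after)), 0.1 * delta)
  expect_lt(mean(abs(after)) / mean(abs(before)), 0.1)
  expect_true(all(abs(after) < abs(before)))
})

test_that("a planted diagnosis effect is preserved", {
  d <- 1.5
  s <- sim_features(n_per_site = 30, site_delta = 2, group_d = d, seed = 31)
  adj <- combat_adjust(s$dat, batch_design(s$site, s$group))
  grp_diff <- rowMeans(adj[, s$group == "case"]) -
    rowMeans(adj[, s$group == "control"])
  # mean over features: systematic attenuation would show here
  expect_lt(abs(mean(grp_diff) - d), 0.1 * d)
})

test_that("EB location estimates shrink toward the pooled prior mean", {
  s <- sim_features(n_per_site = 20, site_delta = 1, seed = 41)
  adj <- combat_adjust(s$dat, batch_design(s$site, s$group))
  est <- attr(adj, "combat")
  for (b in 1:2) {
    lo <- pmin(est$gamma_hat[b, ], est$gamma_bar[b])
    hi <- pmax(est$gamma_hat[b, ], est$gamma_bar[b])
    expect_true(all(est$gamma_star[b, ] >= lo - 1e-12 &
                    est$gamma_star[b, ] <= hi + 1e-12))
  }
})

test_that("adjusting already-adjusted data is a near no-op", {
  # covariate-free design: after one pass the batch estimates are exactly
  # zero, so a second pass is an identity to machine precision
  s <- sim_features(n_per_site = 15, site_delta = 1.5, seed = 51)
  design0 <- batch_design(s$site, rep("control", 30))
  once0 <- combat_adjust(s$dat, design0, eb = FALSE)
  twice0 <- combat_adjust(once0, design0, eb = FALSE)
  expect_lt(sqrt(mean((twice0 - once0)^2)), 1e-6)

  # with the diagnosis covariate and EB shrinkage the identity is only
  # approximate: the second pass changes far less than the first
  design <- batch_design(s$site, s$group)
  once_eb <- combat_adjust(s$dat, design)
  twice_eb <- combat_adjust(once_eb, design)
  expect_lt(sqrt(mean((twice_eb - once_eb)^2)),
            0.1 * sqrt(mean((once_eb - s$dat)^2)))
})

test_that("adjustment is equivariant to subject and feature order", {
  s <- sim_features(n_per_site = 10, site_delta = 1, group_d = 0.5,
                    seed = 61)
  design <- batch_design(s$site, s$group)
  adj <- combat_adjust(s$dat, design)
  perm <- sample(ncol(s$dat))
  adj_p <- combat_adjust(s$dat[, perm],
                         batch_design(s$site[perm], s$group[perm]))
  expect_equal(adj_p, adj[, perm], tolerance = 1e-10, ignore_attr = TRUE)
  fperm <- sample(nrow(s$dat))
  adj_f <- combat_adjust(s$dat[fperm, ], design)
  expect_equal(adj_f, adj[fperm, ], tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("degenerate designs are handled as specified", {
  s <- sim_features(n_per_site = 5, seed = 71)
  expect_warning(
    out <- combat_adjust(s$dat, batch_design(rep("s1", 10), s$group)),
    "single batch")
  expect_equal(out, s$dat, ignore_attr = TRUE)

  expect_error(batch_design(c("s1", rep("s2", 9)), s$group),
               "at least 2")

  dat <- s$dat
  dat[3, ] <- 7                                  # constant feature
  expect_warning(adj <- combat_adjust(dat, batch_design(s$site, s$group)),
                 "constant feature")
  expect_equal(adj[3, ], dat[3, ], ignore_attr = TRUE)

  # diagnosis fully confounded with site: warned at design construction
  expect_warning(batch_design(rep(c("s1", "s2"), each = 5),
                              rep(c("case", "control"), each = 5)),
                 "confounded")

  # age retained only on request
  expect_error(batch_design(s$site, s$group, retain_age = TRUE),
               "requires age")
  d_age <- batch_design(s$site, s$group, age = runif(10, 7, 25),
                        retain_age = TRUE)
  expect_s3_class(d_age, "batch_design")
  expect_silent(combat_adjust(s$dat, d_age))
})
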