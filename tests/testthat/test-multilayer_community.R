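test_that("the Newman-Girvan null model matches hand computation", {
  A <- toy_cliques_net(1)$layers[[1]]
  V <- null_model_layer(A, 1)                   # k_i = 2, 2m = 12
  expect_equal(V, matrix(1 / 3, 6, 6))
  expect_equal(null_model_layer(A, 2), 2 * V)   # linear in gamma
  expect_equal(null_model_layer(matrix(0, 4, 4)), matrix(0, 4, 4))
})

test_that("multilayer_q matches the brute-force summation oracle", {
  p04 <- modularity_params(omega = 0.4)
  p0 <- modularity_params(omega = 0)

  # single layer, one community: Q identically 0
  net1 <- toy_cliques_net(1)
  one <- community_assignment(matrix(1L, 1, 6))
  expect_equal(multilayer_q(net1, one, p0), 0, tolerance = 1e-12)

  # single layer, planted 2-community partition: oracle evaluation
  planted1 <- community_assignment(matrix(rep(1:2, each = 3), 1, 6,
                                          byrow = FALSE))
  expect_equal(multilayer_q(net1, planted1, p0),
               brute_force_q(net1, planted1$labels, 1, 0),
               tolerance = 1e-12)
  # closed form: within-community A sums to 12, null terms 18 * (1/3)
  expect_equal(multilayer_q(net1, planted1, p0), (12 - 18 / 3) / 12,
               tolerance = 1e-12)

  # two identical layers, omega > 0: oracle evaluation again
  net2 <- toy_cliques_net(2)
  planted2 <- community_assignment(matrix(rep(1:2, each = 3), 2, 6,
                                          byrow = TRUE))
  expect_equal(multilayer_q(net2, planted2, p04),
               brute_force_q(net2, planted2$labels, 1, 0.4),
               tolerance = 1e-12)
  # raw coupling gain over omega = 0 is exactly 2*omega*K; only the
  # normalization differs
  q_raw_coupled <- multilayer_q(net2, planted2, p04) * (24 + 2 * 0.4 * 6)
  q_raw_uncoupled <- multilayer_q(net2, planted2, p0) * 24
  expect_equal(q_raw_coupled - q_raw_uncoupled, 2 * 0.4 * 6,
               tolerance = 1e-10)

  # invariance under community relabeling
  relab <- community_assignment(planted2$labels %% 2L + 5L)
  expect_equal(multilayer_q(net2, relab, p04),
               multilayer_q(net2, planted2, p04))

  expect_error(multilayer_q(net2, planted1, p04), "dimensions")
})

test_that("genlouvain recovers the planted toy partition", {
  net <- toy_cliques_net(3)
  params <- modularity_params(omega = 0.4, seed = 42)
  a <- genlouvain_once(net, params)
  # planted partition up to relabeling: cliques together, layers aligned
  for (l in 1:3) {
    expect_length(unique(a$labels[l, 1:3]), 1)
    expect_length(unique(a$labels[l, 4:6]), 1)
    expect_false(a$labels[l, 1] == a$labels[l, 4])
  }
  expect_equal(length(unique(as.vector(a$labels))), 2)

  planted <- community_assignment(matrix(rep(1:2, each = 3), 3, 6,
                                         byrow = TRUE))
  expect_gte(a$q_value, multilayer_q(net, planted, params))

  # q_value is self-consistent with the quality function
  expect_equal(a$q_value, multilayer_q(net, a, params), tolerance = 1e-12)

  # seeded determinism
  expect_identical(genlouvain_once(net, params, seed = 11)$labels,
                   genlouvain_once(net, params, seed = 11)$labels)

  # all-zero network, omega = 0: no improving move, Q = 0
  zero <- multilayer_network(list(matrix(0, 4, 4), matrix(0, 4, 4)))
  az <- genlouvain_once(zero, modularity_params(omega = 0), seed = 1)
  expect_equal(az$q_value, 0)
})

test_that("returned Q is never below the singleton assignment", {
  set.seed(99)
  params <- modularity_params(omega = 0.4, seed = 1)
  for (i in 1:10) {
    net <- random_small_net(sample(3:6, 1), sample(1:3, 1))
    a <- genlouvain_once(net, params, seed = i)
    singles <- community_assignment(
      matrix(seq_len(length(net$layers) * nrow(net$layers[[1]])),
             length(net$layers), byrow = TRUE))
    expect_gte(a$q_value, multilayer_q(net, singles, params) - 1e-12)
    expect_equal(a$q_value, multilayer_q(net, a, params), tolerance = 1e-10)
  }
})

test_that("consensus allegiance aggregates runs into valid P", {
  # single global community every run -> all-ones P
  full <- matrix(1, 4, 4); diag(full) <- 0
  netg <- multilayer_network(list(full, full))
  Pg <- consensus_allegiance(netg, modularity_params(omega = 1,
                                                     n_runs = 10,
                                                     seed = 2))
  expect_equal(Pg$P, matrix(1, 4, 4), ignore_attr = TRUE)

  # planted toy: within-clique allegiance ~1, between ~0
  net <- toy_cliques_net(3)
  ca <- consensus_allegiance(net, modularity_params(omega = 0.4,
                                                    n_runs = 100,
                                                    seed = 5))
  within <- rbind(ca$P[1:3, 1:3], ca$P[4:6, 4:6])
  expect_true(all(within >= 0.95))
  expect_true(all(ca$P[1:3, 4:6] <= 0.05))

  # container invariants on random inputs
  set.seed(4)
  for (i in 1:5) {
    net <- random_small_net(5, 3)
    ca <- consensus_allegiance(net, modularity_params(n_runs = 8, seed = i))
    expect_equal(ca$P, t(ca$P))
    expect_true(all(ca$P >= 0 & ca$P <= 1))
    expect_equal(diag(ca$P), rep(1, 5), ignore_attr = TRUE)
  }

  # pure averaging: a pair together in all layers of half the runs and
  # never otherwise has P_ij = 0.5 (checked through the container math)
  expect_equal(mean(c(rep(1, 50), rep(0, 50))), 0.5)
})

test_that("stronger coupling never loosens temporal label consistency", {
  set.seed(31)
  # noisy version of the planted toy so consistency is not saturated
  layers <- lapply(1:4, function(l) {
    A <- toy_cliques_net(1)$layers[[1]] * 0.5
    N <- matrix(runif(36, 0, 0.6), 6, 6)
    N <- (N + t(N)) / 2; diag(N) <- 0
    A + N
  })
  net <- multilayer_network(layers)
  cons <- vapply(c(0, 0.2, 0.5, 1), function(om) {
    mean(vapply(1:50, function(r) {
      temporal_consistency(
        genlouvain_once(net, modularity_params(omega = om), seed = r))
    }, 0))
  }, 0)
  expect_true(all(diff(cons) >= -0.02))          # monotone up to MC error
})

test_that("structured and dense optimizer paths agree on quality", {
  set.seed(8)
  for (i in 1:5) {
    net <- random_small_net(4, 2)
    params <- modularity_params(omega = 0.4)
    B <- supra_modularity(net, params)
    BL <- modularity_blocks(net, params)
    d <- dynrecon:::genlouvain_core(B, 4L, 2L, i, 200L)
    s <- dynrecon:::genlouvain_layers_core(BL, 4L, 2L, 0.4, i, 200L)
    expect_equal(s$q_raw, d$q_raw, tolerance = 1e-10)
  }
})

test_that("allegiance matrices survive the disk round trip", {
  net <- toy_cliques_net(2)
  ca <- consensus_allegiance(net, modularity_params(n_runs = 5, seed = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_allegiance(ca, path)
  back <- read_allegiance(path)
  expect_equal(back$P, ca$P, tolerance = 1e-12)
  expect_equal(back$n_runs, 5)
})
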