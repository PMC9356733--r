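#' Multilayer modularity parameters
#'
#' @param gamma structural resolution, uniform across layers (> 0).
#'   Default 1.
#' @param omega temporal resolution: weight of the ordinal interlayer
#'   coupling between the same node in adjacent layers (>= 0).  Default 0.4;
#'   the robustness variant uses 1.
#' @param n_runs optimizer repetitions aggregated into the allegiance
#'   matrix.  Default 100.
#' @param seed integer seed; run `r` uses an independent sub-stream derived
#'   from `(seed, r)`.
#' @param max_passes cap on local-move sweeps per aggregation level.
#' @return object of class `modularity_params`.
#' @export
modularity_params <- function(gamma = 1, omega = 0.4, n_runs = 100L,
                              seed = 1L, max_passes = 200L) {
  if (gamma <= 0) stop("gamma must be > 0")
  if (omega < 0) stop("omega must be >= 0")
  if (n_runs < 1) stop("n_runs must be >= 1")
  structure(list(gamma = gamma, omega = omega, n_runs = as.integer(n_runs),
                 seed = as.integer(seed), max_passes = as.integer(max_passes)),
            class = "modularity_params")
}

#' Newman-Girvan null model of one layer
#'
#' Expected edge weight under the configuration model:
#' `gamma * k_i * k_j / (2 m)` with `k_i` the node strength and `m` the
#' total edge weight of the layer.  An all-zero layer returns an all-zero
#' matrix.
#' @param A_l symmetric nonnegative K x K layer.
#' @param gamma structural resolution.
#' @return K x K matrix.
#' @export
null_model_layer <- function(A_l, gamma = 1) {
  k <- rowSums(A_l)
  two_m <- sum(A_l)
  if (two_m == 0) return(matrix(0, nrow(A_l), ncol(A_l)))
  gamma * outer(k, k) / two_m
}

# total normalization 2*mu: intralayer weight plus interlayer coupling
two_mu <- function(net, omega) {
  K <- n_nodes(net); L <- n_layers(net)
  sum(vapply(net$layers, sum, 0)) + 2 * omega * K * max(L - 1, 0)
}

#' Supra-modularity matrix
#'
#' Dense `(K*L) x (K*L)` matrix `B` over node-layer elements (layer-major
#' order): intralayer blocks `A_l - gamma * k k' / (2 m_l)` (including the
#' diagonal null term, which is constant in the partition), and ordinal
#' coupling `omega` linking each node to itself in adjacent layers.
#' Maximizing `sum(B[same community])` is equivalent to maximizing the
#' multilayer modularity quality function.
#' @param net a [multilayer_network()].
#' @param params a [modularity_params()].
#' @return numeric matrix.
#' @export
supra_modularity <- function(net, params) {
  K <- n_nodes(net); L <- n_layers(net)
  B <- matrix(0, K * L, K * L)
  for (l in seq_len(L)) {
    idx <- (l - 1) * K + seq_len(K)
    B[idx, idx] <- net$layers[[l]] -
      null_model_layer(net$layers[[l]], params$gamma)
  }
  if (params$omega > 0 && L > 1) {
    for (l in seq_len(L - 1)) {
      i1 <- (l - 1) * K + seq_len(K)
      i2 <- l * K + seq_len(K)
      B[cbind(i1, i2)] <- params$omega
      B[cbind(i2, i1)] <- params$omega
    }
  }
  B
}

#' Per-layer modularity blocks
#'
#' The K x K x L array of intralayer modularity blocks
#' `A_l - gamma * k k' / (2 m_l)` -- the block-sparse representation of the
#' supra-modularity matrix consumed by the optimizer's fast path (the
#' interlayer coupling is regular and passed separately as `omega`).
#' @inheritParams supra_modularity
#' @return numeric array, dim `c(K, K, L)`.
#' @export
modularity_blocks <- function(net, params) {
  K <- n_nodes(net); L <- n_layers(net)
  BL <- array(0, c(K, K, L))
  for (l in seq_len(L))
    BL[, , l] <- net$layers[[l]] -
      null_model_layer(net$layers[[l]], params$gamma)
  BL
}

#' Community assignment container
#'
#' @param labels L x K integer matrix of community ids (layers in rows).
#' @param q_value achieved multilayer modularity.
#' @return object of class `community_assignment`.
#' @export
community_assignment <- function(labels, q_value = NA_real_) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (any(labels < 1)) stop("community labels must be positive integers")
  structure(list(labels = labels, q_value = q_value),
            class = "community_assignment")
}

#' Evaluate the multilayer modularity quality function
#'
#' Direct evaluation of
#' `Q = (1 / 2mu) * sum_{ijlr} [(A_ijl - gamma * V_ijl) delta_lr +
#'  delta_ij * omega_jlr] * delta(g_il, g_jr)`
#' with per-layer Newman-Girvan null model `V`, ordinal coupling
#' (`omega_jlr = omega` iff `|l - r| == 1` and the same node, else 0), and
#' `2mu` the total intralayer weight plus total interlayer coupling weight.
#' The `i == j` intralayer null term is included (it is constant in the
#' partition).  A fully empty network (`2mu == 0`) scores 0.
#'
#' @param net a [multilayer_network()].
#' @param assign a [community_assignment()] with matching dimensions.
#' @param params a [modularity_params()].
#' @return scalar Q.
#' @export
multilayer_q <- function(net, assign, params) {
  K <- n_nodes(net); L <- n_layers(net)
  g <- assign$labels
  if (!all(dim(g) == c(L, K)))
    stop("assignment dimensions (", paste(dim(g), collapse = " x "),
         ") do not match network (", L, " x ", K, ")")
  q <- 0
  for (l in seq_len(L)) {
    Bl <- net$layers[[l]] - null_model_layer(net$layers[[l]], params$gamma)
    same <- outer(g[l, ], g[l, ], "==")
    q <- q + sum(Bl[same])
  }
  if (L > 1 && params$omega > 0)
    for (l in seq_len(L - 1))
      q <- q + 2 * params$omega * sum(g[l, ] == g[l + 1, ])
  tm <- two_mu(net, params$omega)
  if (tm == 0) 0 else q / tm
}

#' One generalized Louvain run
#'
#' Greedy maximization of multilayer modularity over node-layer elements:
#' randomized-order local moves accepted only on strict improvement,
#' followed by community aggregation, until no improving move exists.
#' Stochastic via the visit order; identical seeds give identical
#' assignments.
#'
#' @inheritParams supra_modularity
#' @param seed integer seed for this run (defaults to `params$seed`).
#' @return a [community_assignment()] whose `q_value` equals
#'   [multilayer_q()] of its labels.
#' @export
genlouvain_once <- function(net, params = modularity_params(),
                            seed = params$seed) {
  BL <- modularity_blocks(net, params)
  res <- genlouvain_layers_core(BL, n_nodes(net), n_layers(net),
                                params$omega, as.integer(seed),
                                params$max_passes)
  tm <- two_mu(net, params$omega)
  q <- if (tm == 0) 0 else res$q_raw / tm
  community_assignment(res$labels, q)
}

#' Consensus module-allegiance matrix
#'
#' Runs the generalized Louvain optimizer `n_runs` times with independent
#' seeded sub-streams; for each run the co-assignment frequency of every
#' node pair across the L layers is recorded, and the allegiance matrix `P`
#' is the mean over runs.  `P_ij` is the relative frequency at which nodes
#' `i` and `j` share a community across the time domain; `P_ii = 1` by
#' construction.
#'
#' @inheritParams supra_modularity
#' @param seed base seed (defaults to `params$seed`).
#' @return object of class `allegiance_matrix`: list with `P` (K x K),
#'   `n_layers`, `n_runs`, `q_mean`, `params`.
#' @export
consensus_allegiance <- function(net, params = modularity_params(),
                                 seed = params$seed) {
  BL <- modularity_blocks(net, params)
  res <- consensus_layers_core(BL, n_nodes(net), n_layers(net),
                               params$omega, params$n_runs,
                               as.integer(seed), params$max_passes)
  tm <- two_mu(net, params$omega)
  P <- res$P
  dimnames(P) <- list(net$nodes, net$nodes)
  allegiance_matrix(P, n_layers = n_layers(net), n_runs = params$n_runs,
                    q_mean = if (tm == 0) 0 else mean(res$q_raw) / tm,
                    params = params)
}

#' Construct / validate an allegiance matrix
#' @param P K x K symmetric matrix in `[0, 1]` with unit diagonal.
#' @param n_layers,n_runs provenance counts.
#' @param q_mean mean modularity across runs.
#' @param params the [modularity_params()] used.
#' @return object of class `allegiance_matrix`.
#' @export
allegiance_matrix <- function(P, n_layers = NA_integer_,
                              n_runs = NA_integer_, q_mean = NA_real_,
                              params = NULL) {
  P <- as.matrix(P)
  if (max(abs(P - t(P))) > 1e-10) stop("allegiance matrix is not symmetric")
  if (any(P < -1e-12 | P > 1 + 1e-12)) stop("allegiance values outside [0, 1]")
  if (max(abs(diag(P) - 1)) > 1e-12) stop("allegiance diagonal must be 1")
  structure(list(P = P, n_layers = n_layers, n_runs = n_runs,
                 q_mean = q_mean, params = params),
            class = "allegiance_matrix")
}

#' @export
print.allegiance_matrix <- function(x, ...) {
  cat("allegiance_matrix:", nrow(x$P), "nodes,", x$n_layers, "layers,",
      x$n_runs, "runs; mean Q =", format(x$q_mean, digits = 4), "\n")
  invisible(x)
}

#' Temporal label consistency
#'
#' Fraction of (node, adjacent-layer) pairs keeping the same community
#' label -- a direct readout of how strongly the interlayer coupling
#' persists labels through time.
#' @param assign a [community_assignment()].
#' @return scalar in `[0, 1]` (`NA` for single-layer assignments).
#' @export
temporal_consistency <- function(assign) {
  g <- assign$labels
  L <- nrow(g)
  if (L < 2) return(NA_real_)
  mean(g[-L, , drop = FALSE] == g[-1, , drop = FALSE])
}

#' Write / read an allegiance matrix
#'
#' Delimited K x K matrix with node-id header plus a JSON sidecar holding
#' gamma, omega, n_runs and the seed.
#' @param x an [allegiance_matrix()].
#' @param path output path for the matrix; the sidecar gets `.json` added.
#' @export
write_allegiance <- function(x, path) {
  utils::write.table(x$P, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  meta <- list(n_layers = x$n_layers, n_runs = x$n_runs, q_mean = x$q_mean,
               gamma = x$params$gamma, omega = x$params$omega,
               seed = x$params$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_allegiance
#' @export
read_allegiance <- function(path) {
  P <- as.matrix(utils::read.delim(path, check.names = FALSE))
  rownames(P) <- colnames(P)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  allegiance_matrix(P,
                    n_layers = meta$n_layers %||% NA_integer_,
                    n_runs = meta$n_runs %||% NA_integer_,
                    q_mean = meta$q_mean %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
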