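# Independent oracles used across the suite.  These deliberately avoid the
# code paths they check: the modularity maximum is found by exhaustive
# enumeration of set partitions, and expected null edge weights come from
# direct resampling.

# --- set-partition enumeration (restricted growth strings) -----------------

.rgs_cache <- new.env(parent = emptyenv())

# all partitions of n labelled elements, one row per partition
rgs_enumerate <- function(n) {
  key <- as.character(n)
  if (!is.null(.rgs_cache[[key]])) return(.rgs_cache[[key]])
  parts <- list(0L)
  if (n > 1) {
    for (i in 2:n) {
      parts <- unlist(lapply(parts, function(p) {
        lapply(0:(max(p) + 1L), function(v) c(p, v))
      }), recursive = FALSE)
    }
  }
  G <- do.call(rbind, parts)
  .rgs_cache[[key]] <- G
  G
}

# exhaustive maximum of multilayer modularity over ALL assignments of
# node-layer elements to communities (vectorized over partitions)
brute_force_max_q <- function(net, params) {
  B <- supra_modularity(net, params)
  n <- nrow(B)
  G <- rgs_enumerate(n)
  q <- rep(0, nrow(G))
  for (a in seq_len(n)) {
    q <- q + B[a, a]
    if (a < n) for (b in (a + 1):n)
      q <- q + 2 * B[a, b] * (G[, a] == G[, b])
  }
  tm <- dynrecon:::two_mu(net, params$omega)
  list(q_max = max(q) / tm,
       labels = matrix(G[which.max(q), ] + 1L,
                       nrow = length(net$layers), byrow = TRUE))
}

# direct summation of the quality function for one assignment (independent
# of both supra_modularity and the C++ core)
brute_force_q <- function(net, labels, gamma, omega) {
  L <- length(net$layers)
  K <- nrow(net$layers[[1]])
  q <- 0
  for (l in seq_len(L)) {
    A <- net$layers[[l]]
    k <- rowSums(A)
    two_m <- sum(A)
    for (i in seq_len(K)) for (j in seq_len(K)) {
      V <- if (two_m == 0) 0 else k[i] * k[j] / two_m
      if (labels[l, i] == labels[l, j]) q <- q + A[i, j] - gamma * V
    }
  }
  if (L > 1) for (l in seq_len(L - 1)) for (i in seq_len(K))
    if (labels[l, i] == labels[l + 1, i]) q <- q + 2 * omega
  tm <- sum(vapply(net$layers, sum, 0)) + 2 * omega * K * max(L - 1, 0)
  if (tm == 0) 0 else q / tm
}

# --- fixtures ---------------------------------------------------------------

# two disjoint 3-cliques (unit weights) replicated over n_layers layers
toy_cliques_net <- function(n_layers = 3) {
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- 1
  A[4:6, 4:6] <- 1
  diag(A) <- 0
  multilayer_network(rep(list(A), n_layers))
}

toy_cliques_partition <- function() {
  node_partition(paste0("n", 1:6), rep(c("cliqueA", "cliqueB"), each = 3))
}

# random small multilayer network with at least one edge per layer
random_small_net <- function(K, L, density = 0.6) {
  layers <- lapply(seq_len(L), function(l) {
    repeat {
      A <- matrix(stats::runif(K * K), K, K)
      A[A < 1 - density] <- 0
      A <- (A + t(A)) / 2
      diag(A) <- 0
      if (sum(A) > 0) return(A)
    }
  })
  multilayer_network(layers)
}

# random symmetric allegiance-like matrix with unit diagonal
random_allegiance <- function(K) {
  P <- matrix(stats::runif(K * K), K, K)
  P <- (P + t(P)) / 2
  diag(P) <- 1
  P
}
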