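#' Node recruitment coefficients
#'
#' Average allegiance of node `i` with the nodes of its own functional
#' network `N`: `R_i = (1 / m_N) * sum_{j in N} P_ij`, with the sum running
#' over all of `N` including `j = i` (the unit diagonal contributes a
#' `1 / m_N` floor, documented rather than removed).
#'
#' @param alleg an [allegiance_matrix()] (or bare K x K matrix with node-id
#'   dimnames).
#' @param part a [node_partition()]; every analysis node must be present in
#'   the allegiance matrix.
#' @return named numeric vector over analysis nodes, values in `[0, 1]`.
#' @export
node_recruitment <- function(alleg, part) {
  P <- alleg_P(alleg, part)
  net <- network_of(part)
  nodes <- names(net)
  out <- stats::setNames(numeric(length(nodes)), nodes)
  for (N in unique(net)) {
    members <- nodes[net == N]
    out[members] <- rowMeans(P[members, members, drop = FALSE])
  }
  out
}

#' Node integration coefficients
#'
#' Average allegiance of node `i` with nodes outside its network:
#' `I_i = (1 / (K - m_N)) * sum_{j not in N} P_ij`.
#' @inheritParams node_recruitment
#' @return named numeric vector over analysis nodes, values in `[0, 1]`.
#' @export
node_integration <- function(alleg, part) {
  P <- alleg_P(alleg, part)
  net <- network_of(part)
  nodes <- names(net)
  K <- length(nodes)
  sz <- network_sizes(part)
  if (any(sz >= K))
    stop("degenerate partition: a network contains all nodes ",
         "(integration undefined)")
  out <- stats::setNames(numeric(length(nodes)), nodes)
  for (N in unique(net)) {
    members <- nodes[net == N]
    foreign <- nodes[net != N]
    out[members] <- rowMeans(P[members, foreign, drop = FALSE])
  }
  out
}

#' Network-level recruitment
#'
#' Unweighted mean of node recruitment over the ROIs of each network.
#' @param r_i named node-recruitment vector from [node_recruitment()].
#' @param part a [node_partition()].
#' @return named numeric vector over networks.
#' @export
network_recruitment <- function(r_i, part) {
  net <- network_of(part)
  nets <- names(network_sizes(part))
  vapply(nets, function(N) mean(r_i[names(net)[net == N]]), 0)
}

#' Pairwise network integration
#'
#' Mean allegiance over cross-network node pairs:
#' `I(N, M) = (1 / (m_N * m_M)) * sum_{i in N} sum_{j in M} P_ij`,
#' symmetric in `(N, M)`; with 9 networks this yields the 36 unordered
#' pairs.  Averaging `I(N, M)` over `M != N` with weights `m_M` recovers
#' the network mean of node integration exactly.
#'
#' @inheritParams node_recruitment
#' @return data.frame with columns `network_1`, `network_2` (lexicographic
#'   order within each pair), `value`.
#' @export
pairwise_network_integration <- function(alleg, part) {
  P <- alleg_P(alleg, part)
  net <- network_of(part)
  nodes <- names(net)
  nets <- names(network_sizes(part))
  pairs <- utils::combn(nets, 2)
  value <- apply(pairs, 2, function(nm) {
    mean(P[nodes[net == nm[1]], nodes[net == nm[2]], drop = FALSE])
  })
  data.frame(network_1 = pairs[1, ], network_2 = pairs[2, ],
             value = value, stringsAsFactors = FALSE)
}

#' Node-level cross-network integration for one network pair
#'
#' For every node of `N`, its mean allegiance with the nodes of `M` (and
#' vice versa); the ROI-level quantity behind a significant pairwise
#' integration result.
#' @inheritParams node_recruitment
#' @param network_1,network_2 two distinct network labels.
#' @return named numeric vector over the nodes of both networks.
#' @export
node_pair_integration <- function(alleg, part, network_1, network_2) {
  if (network_1 == network_2)
    stop("network pair must be two distinct networks ",
         "(same-network allegiance is recruitment)")
  P <- alleg_P(alleg, part)
  net <- network_of(part)
  nodes <- names(net)
  a <- nodes[net == network_1]
  b <- nodes[net == network_2]
  c(rowMeans(P[a, b, drop = FALSE]), rowMeans(P[b, a, drop = FALSE]))
}

#' Per-subject network-level metric rows
#'
#' The 45-parameter summary of one subject (with 9 networks): 9 network
#' recruitment coefficients and 36 pairwise integration coefficients, in
#' the tidy MetricTable layout.
#' @inheritParams node_recruitment
#' @param subject_id identifier copied into the rows.
#' @return data.frame with columns `subject_id`, `metric_type`
#'   (`"recruitment"` or `"integration"`), `network_1`, `network_2` (empty
#'   for recruitment), `value`.
#' @export
subject_metrics <- function(alleg, part, subject_id = "s1") {
  rn <- network_recruitment(node_recruitment(alleg, part), part)
  ip <- pairwise_network_integration(alleg, part)
  rbind(
    data.frame(subject_id = subject_id, metric_type = "recruitment",
               network_1 = names(rn), network_2 = "", value = unname(rn),
               stringsAsFactors = FALSE),
    data.frame(subject_id = subject_id, metric_type = "integration",
               network_1 = ip$network_1, network_2 = ip$network_2,
               value = ip$value, stringsAsFactors = FALSE)
  )
}

#' Reshape a tidy MetricTable to a feature x subject matrix
#'
#' Rows are the network-level parameters (named `recruitment:NET` and
#' `integration:NET1|NET2`), columns are subjects -- the layout consumed by
#' harmonization and group inference.
#' @param metrics tidy MetricTable (rows from [subject_metrics()]).
#' @return numeric matrix, features x subjects.
#' @export
metrics_wide <- function(metrics) {
  key <- ifelse(metrics$metric_type == "recruitment",
                paste0("recruitment:", metrics$network_1),
                paste0("integration:", metrics$network_1, "|",
                       metrics$network_2))
  subjects <- unique(metrics$subject_id)
  feats <- unique(key)
  M <- matrix(NA_real_, length(feats), length(subjects),
              dimnames = list(feats, subjects))
  M[cbind(match(key, feats), match(metrics$subject_id, subjects))] <-
    metrics$value
  if (anyNA(M)) {
    idx <- which(is.na(M), arr.ind = TRUE)[1, ]
    stop("missing metric '", feats[idx[1]], "' for subject '",
         subjects[idx[2]], "'")
  }
  M
}

#' Tidy MetricTable from a feature x subject matrix
#' @param wide matrix from [metrics_wide()].
#' @return tidy MetricTable data.frame.
#' @export
metrics_tidy <- function(wide) {
  parts <- strsplit(rownames(wide), "[:|]")
  do.call(rbind, lapply(seq_len(ncol(wide)), function(j) {
    data.frame(subject_id = colnames(wide)[j],
               metric_type = vapply(parts, `[`, "", 1),
               network_1 = vapply(parts, `[`, "", 2),
               network_2 = vapply(parts, function(p)
                 if (length(p) > 2) p[3] else "", ""),
               value = wide[, j], row.names = NULL,
               stringsAsFactors = FALSE)
  }))
}

# extract the P matrix and check node coverage against the partition
alleg_P <- function(alleg, part) {
  P <- if (inherits(alleg, "allegiance_matrix")) alleg$P else as.matrix(alleg)
  nodes <- analysis_nodes(part)
  if (is.null(rownames(P))) {
    if (nrow(P) != length(nodes))
      stop("allegiance matrix size does not match partition")
    dimnames(P) <- list(nodes, nodes)
  }
  miss <- setdiff(nodes, rownames(P))
  if (length(miss))
    stop("nodes missing from allegiance matrix: ",
         paste(miss, collapse = ", "))
  P[nodes, nodes]
}
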