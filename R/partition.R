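#' Node-to-network partitions
#'
#' A `node_partition` maps each ROI (node) of an atlas to exactly one of a
#' small set of predefined functional networks, and flags nodes that are
#' excluded from analysis (typically cerebellar parcels).  All downstream
#' stages -- connectivity, community detection, recruitment/integration --
#' operate on the non-excluded nodes in the order given here.
#'
#' @param node_id character or integer vector of unique node identifiers.
#' @param network network label per node; must be non-empty for every
#'   non-excluded node.
#' @param excluded logical vector; `TRUE` drops the node from the analysis
#'   set (e.g. cerebellum).
#' @return An object of class `node_partition`: a data.frame with columns
#'   `node_id`, `network`, `excluded`.
#' @examples
#' p <- node_partition(paste0("n", 1:6), rep(c("DMN", "BGN"), each = 3))
#' network_sizes(p)
#' @export
node_partition <- function(node_id, network, excluded = FALSE) {
  node_id <- as.character(node_id)
  network <- as.character(network)
  excluded <- rep_len(as.logical(excluded), length(node_id))
  if (anyDuplicated(node_id))
    stop("duplicate node ids: ",
         paste(unique(node_id[duplicated(node_id)]), collapse = ", "))
  if (length(network) != length(node_id))
    stop("'network' must have one label per node")
  bad <- !excluded & (is.na(network) | network == "")
  if (any(bad))
    stop("non-excluded nodes with empty network label: ",
         paste(node_id[bad], collapse = ", "))
  p <- data.frame(node_id = node_id, network = network,
                  excluded = excluded, stringsAsFactors = FALSE)
  class(p) <- c("node_partition", "data.frame")
  sz <- network_sizes(p)
  if (any(sz < 2))
    stop("network sizes must be >= 2; too small: ",
         paste(names(sz)[sz < 2], collapse = ", "))
  p
}

#' @export
print.node_partition <- function(x, ...) {
  sz <- network_sizes(x)
  cat("node_partition:", sum(!x$excluded), "analysis nodes (",
      sum(x$excluded), "excluded ) in", length(sz), "networks\n")
  print(sz)
  invisible(x)
}

#' Analysis nodes of a partition
#'
#' Node ids retained for analysis (exclusion flag off), in partition order.
#' @param part a [node_partition()].
#' @return character vector of node ids.
#' @export
analysis_nodes <- function(part) part$node_id[!part$excluded]

#' Network sizes
#'
#' Number of analysis nodes per network (`m_N`).
#' @inheritParams analysis_nodes
#' @return named integer vector.
#' @export
network_sizes <- function(part) {
  keep <- !part$excluded
  tab <- table(part$network[keep])
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Network label per analysis node
#' @inheritParams analysis_nodes
#' @return named character vector (names = node ids).
#' @export
network_of <- function(part) {
  keep <- !part$excluded
  stats::setNames(part$network[keep], part$node_id[keep])
}

#' Read / write a partition table
#'
#' Delimited text with columns `node_id`, `network`, `excluded` (0/1 or
#' logical).  Excluded nodes keep their row but are dropped from the
#' analysis set.
#' @param path file path.
#' @return [read_partition()] returns a [node_partition()];
#'   [write_partition()] returns `path` invisibly.
#' @export
read_partition <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("node_id", "network", "excluded")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("partition file missing columns: ", paste(miss, collapse = ", "))
  node_partition(tab$node_id, tab$network, as.logical(tab$excluded))
}

#' @rdname read_partition
#' @param part a [node_partition()].
#' @export
write_partition <- function(part, path) {
  out <- data.frame(node_id = part$node_id, network = part$network,
                    excluded = as.integer(part$excluded))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# canonical nine functional-network labels used throughout
NINE_NETWORKS <- c("DMN", "MFN", "FPN", "limbic", "motor",
                   "visual1", "visual2", "visual_assoc", "BGN")

#' Default 268-node synthetic partition
#'
#' A deterministic stand-in for a 268-parcel whole-brain atlas: 49 nodes are
#' flagged cerebellar (excluded) and the remaining 219 are assigned to nine
#' functional networks (DMN, MFN, FPN, limbic, motor, visual I/II, visual
#' association, BGN).  The network sizes are plausible but synthetic -- this
#' is NOT a real atlas lookup table; it exists so the pipeline's structural
#' bookkeeping (219 x 219 adjacency, 9 + 36 = 45 network-level parameters)
#' can be exercised without atlas data.  The same table ships as
#' `inst/extdata/partition_268node_9net_synthetic.tsv`.
#'
#' @return a [node_partition()] with 268 rows, 219 analysis nodes.
#' @export
default_partition <- function() {
  sizes <- c(DMN = 38, MFN = 20, FPN = 28, limbic = 24, motor = 27,
             visual1 = 14, visual2 = 16, visual_assoc = 24, BGN = 28)
  stopifnot(sum(sizes) == 219)
  network <- c(rep(names(sizes), sizes), rep("cerebellum", 49))
  node_id <- sprintf("roi%03d", seq_along(network))
  node_partition(node_id, network,
                 excluded = network == "cerebellum")
}

#' Small partition for synthetic cohorts
#'
#' Nine networks with `n_per_network` nodes each; the desk-scale default
#' world of the synthetic-cohort generator.
#' @param n_per_network nodes per network (>= 2).
#' @return a [node_partition()].
#' @export
toy_partition <- function(n_per_network = 5) {
  stopifnot(n_per_network >= 2)
  network <- rep(NINE_NETWORKS, each = n_per_network)
  node_id <- sprintf("%s_%02d", network, sequence(rep(n_per_network, 9)))
  node_partition(node_id, network)
}
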