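#' Sliding-window scheme
#'
#' Consecutive fixed-length windows over `1..n_timepoints`, stored as 0-based
#' half-open `[start, end)` index ranges.  The defaults (length 20 TR, step
#' 10 TR) give 50% overlap between contiguous windows; trailing timepoints
#' not covered by a full window are dropped.
#'
#' @param n_timepoints total timepoints `T`.
#' @param length window length in timepoints.
#' @param step offset between window starts; `floor(length / 2)` gives the
#'   default 50% overlap.
#' @return object of class `window_scheme`: list with `length`, `step`, and
#'   `windows`, an n x 2 matrix of `[start, end)` pairs.
#' @examples
#' make_windows(100)           # 9 windows starting 0, 10, ..., 80
#' @export
make_windows <- function(n_timepoints, length = 20L, step = floor(length / 2)) {
  length <- as.integer(length); step <- as.integer(step)
  if (length < 1 || step < 1) stop("window length and step must be >= 1")
  if (n_timepoints < length)
    stop("insufficient data: T = ", n_timepoints,
         " is shorter than one window of length ", length)
  n_win <- (n_timepoints - length) %/% step + 1L
  starts <- (seq_len(n_win) - 1L) * step
  structure(list(length = length, step = step,
                 windows = cbind(start = starts, end = starts + length)),
            class = "window_scheme")
}

#' @export
print.window_scheme <- function(x, ...) {
  cat("window_scheme:", nrow(x$windows), "windows of length", x$length,
      "(step", x$step, ")\n")
  invisible(x)
}

#' Multilayer network from windowed connectivity
#'
#' Pearson correlation between every pair of nodes within each window;
#' negative correlations are set to 0 (their network interpretation is
#' unclear) and the diagonal is zeroed (self-edges carry no information in
#' modularity).  One symmetric nonnegative K x K layer per window, in window
#' order, forms the multilayer network.
#'
#' @param ts T x K numeric matrix, columns named by node id; no missing
#'   values; every column must have nonzero variance inside every window.
#' @param scheme a [make_windows()] scheme.
#' @return object of class `multilayer_network`: list with `layers` (list of
#'   K x K matrices), `scheme`, `nodes`.
#' @export
window_connectivity <- function(ts, scheme) {
  stopifnot(inherits(scheme, "window_scheme"))
  ts <- as.matrix(ts)
  if (anyNA(ts)) stop("time series contains missing values")
  nodes <- colnames(ts)
  if (is.null(nodes)) nodes <- sprintf("n%d", seq_len(ncol(ts)))
  layers <- vector("list", nrow(scheme$windows))
  for (w in seq_along(layers)) {
    rows <- (scheme$windows[w, "start"] + 1L):scheme$windows[w, "end"]
    x <- ts[rows, , drop = FALSE]
    xc <- sweep(x, 2, colMeans(x))
    ss <- colSums(xc^2)
    if (any(ss == 0))
      stop("zero-variance column in window ", w, " (node ",
           paste(nodes[ss == 0], collapse = ", "),
           "): degenerate input")
    A <- crossprod(xc / rep(sqrt(ss), each = nrow(xc)))
    A[A < 0] <- 0
    diag(A) <- 0
    dimnames(A) <- list(nodes, nodes)
    layers[[w]] <- A
  }
  multilayer_network(layers, scheme, nodes)
}

#' Construct / validate a multilayer network
#'
#' @param layers list of K x K symmetric nonnegative matrices with zero
#'   diagonal, in temporal order.
#' @param scheme the [make_windows()] scheme that produced them (optional
#'   for hand-built networks).
#' @param nodes node ids in matrix order.
#' @return object of class `multilayer_network`.
#' @export
multilayer_network <- function(layers, scheme = NULL, nodes = NULL) {
  stopifnot(is.list(layers), length(layers) >= 1)
  K <- nrow(layers[[1]])
  if (is.null(nodes)) nodes <- colnames(layers[[1]])
  if (is.null(nodes)) nodes <- sprintf("n%d", seq_len(K))
  for (l in seq_along(layers)) {
    A <- layers[[l]]
    if (!is.matrix(A) || nrow(A) != K || ncol(A) != K)
      stop("layer ", l, " is not a ", K, " x ", K, " matrix")
    if (max(abs(A - t(A))) > 1e-10) stop("layer ", l, " is not symmetric")
    if (any(A < 0)) stop("layer ", l, " has negative entries")
    if (any(diag(A) != 0)) stop("layer ", l, " has nonzero diagonal")
  }
  structure(list(layers = layers, scheme = scheme, nodes = nodes),
            class = "multilayer_network")
}

#' @export
print.multilayer_network <- function(x, ...) {
  cat("multilayer_network:", length(x$layers), "layers x",
      length(x$nodes), "nodes\n")
  invisible(x)
}

n_layers <- function(net) length(net$layers)
n_nodes <- function(net) length(net$nodes)
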