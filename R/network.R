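#' Cluster labels from an NMF basis matrix
#'
#' Each column of the r x p basis matrix `H` (one column per variable) is
#' assigned to the component with the largest coefficient; ties break to
#' the lowest component index. An all-zero column carries no information
#' and is assigned to component 1 with a warning.
#'
#' @param H Non-negative r x p matrix.
#' @return Integer vector of p labels in `1..r`.
#' @export
cluster_labels <- function(H) {
  H <- as.matrix(H)
  if (min(H) < 0) stop("`H` must be non-negative", call. = FALSE)
  zero <- colSums(H) == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero column(s) in H assigned to cluster 1")
  }
  apply(H, 2L, which.max)  # which.max breaks ties to the lowest index
}

#' Consensus matrix over repeated NMF clusterings of a stationary segment
#'
#' Fits NMF `nruns` times from independent random initializations, derives
#' cluster labels from each basis matrix, forms the binary co-membership
#' adjacency per run, and averages. Entry `C_ij` estimates the probability
#' that variables i and j cluster together, pooling runs that individually
#' may sit in poor local optima (in the spirit of stability selection).
#'
#' @param segment Non-negative numeric matrix (rows = time points of one
#'   stationary segment).
#' @param rank NMF rank (typically the rank selected during change point
#'   detection).
#' @param nruns Number of independent fits averaged (default 100).
#' @inheritParams fit_nmf
#' @return Object of class `consensus_matrix`: list with `values` (p x p,
#'   symmetric, entries in `[0, 1]`, unit diagonal) and `nruns`.
#' @export
consensus <- function(segment, rank, nruns = 100, max_iter = 200,
                      tol = 1e-4) {
  segment <- as.matrix(segment)
  if (nruns < 1L) stop("`nruns` must be at least 1", call. = FALSE)
  p <- ncol(segment)
  acc <- matrix(0, p, p)
  for (k in seq_len(nruns)) {
    fit <- fit_nmf(segment, rank, 1L, max_iter, tol)
    lbl <- cluster_labels(fit$H)
    acc <- acc + (outer(lbl, lbl, `==`) * 1)
  }
  values <- acc / nruns
  dimnames(values) <- list(colnames(segment), colnames(segment))
  structure(list(values = values, nruns = nruns),
            class = "consensus_matrix")
}

.consensus_values <- function(C) {
  if (inherits(C, "consensus_matrix")) C$values else as.matrix(C)
}

#' Binary network from a consensus matrix by hierarchical clustering
#'
#' Runs complete-linkage hierarchical clustering on the dissimilarity
#' `1 - C`, cuts the tree at `K0` clusters, and connects every pair of
#' variables in the same final cluster (no self-loops).
#'
#' @param C A `consensus_matrix` or plain p x p matrix.
#' @param K0 Number of clusters to cut at, `1 <= K0 <= p`.
#' @return Object of class `cpt_network`: list with `adjacency` (binary,
#'   symmetric, zero diagonal), `method = "clustering-cut"`, `K0` and the
#'   cluster `labels`.
#' @export
network_by_clustering <- function(C, K0) {
  cm <- .consensus_values(C)
  p <- ncol(cm)
  if (K0 < 1L || K0 > p) {
    stop("`K0` must be between 1 and p = ", p, call. = FALSE)
  }
  hc <- stats::hclust(stats::as.dist(1 - cm), method = "complete")
  lbl <- stats::cutree(hc, k = K0)
  adjacency <- (outer(lbl, lbl, `==`)) * 1
  diag(adjacency) <- 0
  dimnames(adjacency) <- dimnames(cm)
  structure(list(adjacency = adjacency, method = "clustering-cut",
                 K0 = as.integer(K0), labels = lbl),
            class = "cpt_network")
}

#' Binary network from a consensus matrix by thresholding
#'
#' Keeps an edge where the consensus probability strictly exceeds
#' `lambda`; the threshold directly controls network sparsity. The
#' diagonal is zeroed (no self-loops).
#'
#' @param C A `consensus_matrix` or plain p x p matrix.
#' @param lambda Threshold in `[0, 1]`.
#' @return Object of class `cpt_network` with `method = "threshold"`.
#' @export
network_by_threshold <- function(C, lambda) {
  if (lambda < 0 || lambda > 1) {
    stop("`lambda` must be in [0, 1]", call. = FALSE)
  }
  cm <- .consensus_values(C)
  adjacency <- (cm > lambda) * 1
  diag(adjacency) <- 0
  dimnames(adjacency) <- dimnames(cm)
  structure(list(adjacency = adjacency, method = "threshold",
                 lambda = lambda),
            class = "cpt_network")
}

#' @export
print.cpt_network <- function(x, ...) {
  p <- ncol(x$adjacency)
  cat(sprintf("Binary network on %d nodes (%s), %d edges\n", p, x$method,
              sum(x$adjacency[upper.tri(x$adjacency)])))
  invisible(x)
}

#' Per-node degrees of a binary network
#'
#' @param net A `cpt_network` or plain adjacency matrix.
#' @return Named integer vector of node degrees.
#' @export
node_degrees <- function(net) {
  adj <- if (inherits(net, "cpt_network")) net$adjacency else as.matrix(net)
  rowSums(adj)
}

#' Aggregate several binary networks by edge frequency
#'
#' Sums edge indicators across networks and keeps edges whose frequency
#' strictly exceeds the given percentile of off-diagonal frequencies —
#' useful for pooling stationary-segment networks across runs or subjects
#' into one sparse summary graph.
#'
#' @param nets List of `cpt_network` objects or adjacency matrices with
#'   identical dimensions.
#' @param percentile Frequency percentile used as cutoff (default 0.999).
#' @return List with `adjacency` (binary aggregate), `counts` (edge
#'   frequencies) and `cutoff`.
#' @export
aggregate_networks <- function(nets, percentile = 0.999) {
  adjs <- lapply(nets, function(n) {
    if (inherits(n, "cpt_network")) n$adjacency else as.matrix(n)
  })
  counts <- Reduce(`+`, adjs)
  cutoff <- stats::quantile(counts[upper.tri(counts)], percentile,
                            names = FALSE)
  adjacency <- (counts > cutoff) * 1
  diag(adjacency) <- 0
  list(adjacency = adjacency, counts = counts, cutoff = cutoff)
}

#' Estimate a network for every stationary segment of a detection result
#'
#' Splits the (shifted) series at the detected change points and estimates
#' one consensus matrix and one binary network per segment, by clustering
#' cut (at `K0`) or thresholding (at `lambda`).
#'
#' @param x The input matrix given to [detect_change_points()].
#' @param result The corresponding `nmf_cpt` object.
#' @param nruns NMF runs per consensus matrix (default 100).
#' @param method `"cut"` or `"threshold"`.
#' @param K0 Clusters for the cut method; defaults to the rank used in
#'   detection.
#' @param lambda Threshold for the threshold method (default 0.5).
#' @param rank NMF rank; defaults to the rank used in detection.
#' @inheritParams fit_nmf
#' @return List with one element per segment: `start`, `end`, `consensus`
#'   and `network`.
#' @export
segment_networks <- function(x, result, nruns = 100,
                             method = c("cut", "threshold"), K0 = NULL,
                             lambda = 0.5, rank = NULL, max_iter = 200,
                             tol = 1e-4) {
  method <- match.arg(method)
  X <- shift_nonnegative(as.matrix(x),
                         margin = result$params$shift_margin)
  if (is.null(rank)) rank <- result$rank_used
  if (is.null(K0)) K0 <- result$rank_used
  bounds <- c(0L, result$change_points, nrow(X))
  out <- vector("list", length(bounds) - 1L)
  for (s in seq_len(length(bounds) - 1L)) {
    seg <- X[(bounds[s] + 1L):bounds[s + 1L], , drop = FALSE]
    cm <- consensus(seg, rank, nruns, max_iter, tol)
    net <- if (method == "cut") {
      network_by_clustering(cm, K0)
    } else {
      network_by_threshold(cm, lambda)
    }
    out[[s]] <- list(start = bounds[s] + 1L, end = bounds[s + 1L],
                     consensus = cm, network = net)
  }
  out
}
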