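#' Build the single-cell K-nearest-neighbour affinity graph
#'
#' Exact KNN search with a locally adaptive Gaussian kernel: the directed
#' affinity from cell i to neighbour j is `exp(-d_ij^2 / sigma_i^2)` where
#' `sigma_i` is the mean distance from i to its K neighbours. Directed
#' affinities are symmetrised by union (elementwise maximum), which preserves
#' edges into rare populations.
#'
#' @param X Numeric cells x features matrix (rows are cells).
#' @param k Number of neighbours per cell, `0 < k < n_cells`.
#' @param metric `"euclidean"` or `"cosine"`.
#' @return An object of class `sc_knn_graph`: list with `adj` (symmetric
#'   sparse affinity matrix, zero diagonal), `k`, `metric`, `n`.
#' @export
build_knn_graph <- function(X, k, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  X <- as.matrix(X)
  check_feature_matrix(X)
  n <- nrow(X)
  if (k <= 0L || k >= n) stop("k must satisfy 0 < k < n_cells; got k=", k,
                              ", n=", n)
  d2 <- pairwise_dist2(X, metric)
  diag(d2) <- Inf
  # k nearest neighbours per cell (ties broken by index for determinism)
  nn <- t(apply(d2, 1L, function(r) order(r)[seq_len(k)]))
  nn_d2 <- matrix(d2[cbind(rep(seq_len(n), k), as.vector(nn))], n, k)
  sigma2 <- rowMeans(sqrt(nn_d2))^2
  sigma2[sigma2 == 0] <- 1e-12       # duplicated points
  w <- exp(-nn_d2 / sigma2)
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn),
                            x = as.vector(w), dims = c(n, n))
  A <- pmax_sparse(A, Matrix::t(A))  # union symmetrisation
  dimnames(A) <- list(rownames(X), rownames(X))
  structure(list(adj = A, k = as.integer(k), metric = metric, n = n),
            class = "sc_knn_graph")
}

# squared distances; cosine uses d^2 = 2(1 - cosine similarity)
pairwise_dist2 <- function(X, metric) {
  if (metric == "euclidean") {
    s <- rowSums(X^2)
    d2 <- outer(s, s, "+") - 2 * tcrossprod(X)
    pmax(d2, 0)
  } else {
    nrm <- sqrt(rowSums(X^2))
    nrm[nrm == 0] <- 1
    cs <- tcrossprod(X / nrm)
    pmax(2 * (1 - pmin(cs, 1)), 0)
  }
}

pmax_sparse <- function(A, B) {
  # exact elementwise max of two nonnegative sparse matrices (no arithmetic
  # on values, so max(A, t(A)) is exactly symmetric)
  A <- methods::as(A, "TsparseMatrix")
  B <- methods::as(B, "TsparseMatrix")
  i <- c(A@i, B@i)
  j <- c(A@j, B@j)
  x <- c(A@x, B@x)
  key <- as.numeric(i) * ncol(A) + j
  ord <- order(key, -x)
  first <- !duplicated(key[ord])
  Matrix::drop0(Matrix::sparseMatrix(i = i[ord][first] + 1L,
                                     j = j[ord][first] + 1L,
                                     x = x[ord][first], dims = dim(A)))
}

#' Cluster cells on the KNN graph or feature matrix
#'
#' `method = "community_detection"` runs Leiden modularity optimisation on the
#' weighted symmetrised KNN graph; `method = "kmeans"` runs k-means on the
#' feature matrix. Labels are returned 0-based and contiguous, in order of
#' first appearance along the cell ordering.
#'
#' @param g An `sc_knn_graph` (required for community detection).
#' @param X Feature matrix (required for kmeans).
#' @param method `"community_detection"` or `"kmeans"`.
#' @param resolution Leiden resolution (> 0).
#' @param centers Number of kmeans clusters (>= 1).
#' @param seed Integer seed.
#' @return Object of class `cluster_assignment`: list with `labels` (integer,
#'   0-based, one per cell) and `n_clusters`.
#' @export
cluster_cells <- function(g = NULL, X = NULL,
                          method = c("community_detection", "kmeans"),
                          resolution = 1.0, centers = NULL, seed = 42L) {
  method <- match.arg(method)
  if (method == "community_detection") {
    if (is.null(g)) stop("community detection requires the KNN graph g")
    if (resolution <= 0) stop("resolution must be > 0")
    ig <- igraph::graph_from_adjacency_matrix(g$adj, mode = "undirected",
                                              weighted = TRUE)
    if (igraph::vcount(ig) == 0L) stop("empty graph")
    set.seed(seed)
    cl <- igraph::cluster_leiden(ig, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 5L)
    labels <- igraph::membership(cl)
  } else {
    if (is.null(X)) stop("kmeans requires the feature matrix X")
    X <- as.matrix(X)
    if (is.null(centers) || centers < 1L) stop("kmeans requires centers >= 1")
    set.seed(seed)
    labels <- stats::kmeans(X, centers = centers, nstart = 10L,
                            iter.max = 100L)$cluster
  }
  labels <- match(labels, unique(labels)) - 1L  # contiguous, 0-based
  structure(list(labels = as.integer(labels),
                 n_clusters = length(unique(labels))),
            class = "cluster_assignment")
}

#' Aggregate the single-cell graph into a weighted cluster graph
#'
#' Edge weight between clusters i and j is the sum (default) or mean of the
#' single-cell affinities connecting them; the diagonal is zero. With
#' `prune_frac > 0`, an edge is removed when its weight is below `prune_frac`
#' times the strongest incident edge of *both* endpoints; maximum spanning
#' forest edges are always kept so pruning never disconnects a component.
#'
#' @param g An `sc_knn_graph`.
#' @param a A `cluster_assignment` covering all cells of `g`.
#' @param aggregation `"sum"` or `"mean"`.
#' @param prune_frac Weak-edge pruning threshold as a fraction of the median
#'   edge weight; 0 disables pruning.
#' @return Object of class `cluster_graph`: list with `W` (dense symmetric
#'   weight matrix, dimnames = cluster ids as characters), `n`, `sizes`
#'   (cells per cluster).
#' @export
build_cluster_graph <- function(g, a, aggregation = c("sum", "mean"),
                                prune_frac = 0) {
  aggregation <- match.arg(aggregation)
  if (length(a$labels) != g$n) stop("assignment does not cover all cells")
  nc <- a$n_clusters
  M <- Matrix::sparseMatrix(i = seq_len(g$n), j = a$labels + 1L, x = 1,
                            dims = c(g$n, nc))
  W <- as.matrix(Matrix::t(M) %*% g$adj %*% M)
  if (aggregation == "mean") {
    cnt <- as.matrix(Matrix::t(M) %*% (g$adj != 0) %*% M)
    W <- ifelse(cnt > 0, W / pmax(cnt, 1), 0)
  }
  W <- (W + t(W)) / 2
  diag(W) <- 0
  dimnames(W) <- list(as.character(0:(nc - 1L)), as.character(0:(nc - 1L)))
  if (prune_frac > 0 && any(W > 0)) W <- prune_weak_edges(W, prune_frac)
  structure(list(W = W, n = nc, sizes = tabulate(a$labels + 1L, nc)),
            class = "cluster_graph")
}

# drop edges that are weak relative to BOTH endpoints' strongest incident
# edge (below frac * min of the two maxima); genuine weak closures on sparse
# rings survive because they are each endpoint's best or near-best link,
# while spurious long-range edges between well-connected hubs fail both
# tests. Maximum-spanning-forest edges are always kept, so pruning never
# disconnects a component.
prune_weak_edges <- function(W, frac) {
  mx <- apply(W, 1L, max)
  thr <- frac * outer(mx, mx, pmin)
  ig <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                            weighted = TRUE)
  msf <- igraph::mst(ig, weights = -igraph::E(ig)$weight)
  keep <- igraph::as_edgelist(msf, names = FALSE)
  Wk <- W
  Wk[W < thr] <- 0
  Wk[keep] <- W[keep]
  Wk[keep[, 2:1, drop = FALSE]] <- W[keep]
  Wk
}

#' Resolve the root cluster
#'
#' Three modes: `cell_index` takes the cluster of that cell (1-based index
#' into the cell ordering); `cluster_id` passes a cluster id through;
#' `group_label` finds the cluster(s) in which the given annotation label is
#' the majority (falling back to the cluster with the highest label fraction
#' when none reaches 50%), breaking ties by root-like connectivity on the
#' cluster graph: higher degree, lower betweenness, then lower cluster id.
#'
#' @param cg A `cluster_graph`.
#' @param a A `cluster_assignment`.
#' @param value Cell index, cluster id, or group label according to `mode`.
#' @param mode One of `"cell_index"`, `"group_label"`, `"cluster_id"`.
#' @param annotations Per-cell labels, required for `group_label` mode.
#' @return A single cluster id (integer, 0-based).
#' @export
select_root <- function(cg, a, value, mode = c("cell_index", "group_label",
                                               "cluster_id"),
                        annotations = NULL) {
  mode <- match.arg(mode)
  if (mode == "cell_index") {
    i <- as.integer(value)
    if (i < 1L || i > length(a$labels)) stop("cell index out of range: ", value)
    return(a$labels[i])
  }
  if (mode == "cluster_id") {
    id <- as.integer(value)
    if (id < 0L || id >= cg$n) stop("no such cluster: ", value)
    return(id)
  }
  if (is.null(annotations)) stop("group_label mode requires annotations")
  if (!value %in% annotations) stop("label not present in annotations: ", value)
  frac <- vapply(0:(cg$n - 1L), function(c)
    mean(annotations[a$labels == c] == value), numeric(1))
  cand <- which(frac > 0.5) - 1L
  if (length(cand) == 0L) cand <- which(frac == max(frac)) - 1L
  if (length(cand) == 1L) return(cand)
  # tie-break: root-like nodes have high degree and low betweenness
  ig <- igraph::graph_from_adjacency_matrix(cg$W, mode = "undirected",
                                            weighted = TRUE)
  deg <- igraph::strength(ig)
  btw <- igraph::betweenness(ig, weights = rep(1, igraph::ecount(ig)))
  score <- rank(-deg[cand + 1L], ties.method = "min") +
    rank(btw[cand + 1L], ties.method = "min")
  cand[order(score, cand)][1L]
}

#' Connected components of a cluster graph
#' @param cg A `cluster_graph`.
#' @return Integer vector of component ids (1-based) per cluster.
#' @export
cluster_components <- function(cg) {
  ig <- igraph::graph_from_adjacency_matrix(cg$W > 0, mode = "undirected")
  as.integer(igraph::components(ig)$membership)
}

#' @export
print.sc_knn_graph <- function(x, ...) {
  cat("Single-cell KNN graph:", x$n, "cells, k =", x$k,
      sprintf("(%s), %d undirected edges\n", x$metric,
              Matrix::nnzero(x$adj) %/% 2L))
  invisible(x)
}

#' @export
print.cluster_graph <- function(x, ...) {
  cat("Cluster graph:", x$n, "nodes,", sum(x$W[upper.tri(x$W)] > 0),
      "edges\n")
  invisible(x)
}
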