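#' Fit a trajectory by lazy-teleporting random walks
#'
#' End-to-end estimator: builds the single-cell KNN graph, clusters it,
#' aggregates the weighted cluster graph, computes root-anchored pseudotime
#' as closed-form hitting times of the lazy-teleporting random walk, refines
#' it by Monte Carlo walks on the forward-biased directed graph, detects
#' terminal states by consensus vote, estimates lineage likelihoods from walk
#' visitation frequencies, and projects pseudotime and lineage probabilities
#' onto single cells. Disconnected data is handled per connected component;
#' components not containing the requested root are anchored at their node of
#' maximal eccentricity.
#'
#' @param X Cells x features numeric matrix (counts or reduced dimensions).
#' @param root Root specification value (see `root_mode`).
#' @param root_mode `"cell_index"` (1-based cell row), `"group_label"`
#'   (requires `annotations`) or `"cluster_id"`.
#' @param annotations Optional per-cell labels for `group_label` root mode.
#' @param k KNN neighbour count (default 30).
#' @param n_pcs If non-NULL, reduce to this many principal components first.
#' @param log1p Apply `log1p` before PCA/KNN (for count data).
#' @param cluster_method,resolution,centers Passed to [cluster_cells()].
#' @param metric KNN distance metric.
#' @param aggregation Cluster edge aggregation (`"sum"` or `"mean"`).
#' @param prune_frac Weak-edge pruning fraction for the cluster graph
#'   (default 0.3; the maximum spanning forest is always kept).
#' @param x,alpha,b,n_mcmc,max_steps Walk parameters, see [walk_config()].
#' @param n_smooth Smoothing passes for single-cell projection.
#' @param seed Integer seed threaded through clustering and all walks.
#' @return Object of class `trajwalk`. Key fields: `pseudotime` (cluster
#'   data frame with `t_closed`, `t_refined`), `pseudotime_cells`,
#'   `terminals`, `terminal_ledger`, `lineage_clusters`, `lineage_cells`,
#'   `cluster_graph`, `directed_graph`, `assignment`, `knn`, `components`,
#'   `roots`, `config`.
#' @examples
#' sim <- simulate_trajectory(topology_spec("bifurcation", n_cells = 200,
#'                                          n_features = 60, seed = 1))
#' fit <- trajwalk(sim$X, root = "M1", root_mode = "group_label",
#'                 annotations = sim$ref$cells$type, k = 10, n_pcs = 5,
#'                 log1p = TRUE, n_mcmc = 200, seed = 1)
#' fit
#' @export
trajwalk <- function(X, root, root_mode = c("cell_index", "group_label",
                                            "cluster_id"),
                     annotations = NULL, k = 30L, n_pcs = NULL,
                     log1p = FALSE,
                     cluster_method = c("community_detection", "kmeans"),
                     resolution = 1.0, centers = NULL,
                     metric = c("euclidean", "cosine"),
                     aggregation = c("sum", "mean"), prune_frac = 0.3,
                     x = 0.95, alpha = 0.99, b = 1, n_mcmc = 1000L,
                     max_steps = NULL, n_smooth = 1L, seed = 42L) {
  root_mode <- match.arg(root_mode)
  cluster_method <- match.arg(cluster_method)
  metric <- match.arg(metric)
  aggregation <- match.arg(aggregation)
  cl <- match.call()
  X <- as.matrix(X)
  if (is.null(rownames(X))) rownames(X) <- paste0("cell_", seq_len(nrow(X)) - 1L)
  Xw <- if (log1p) log1p(X) else X
  if (!is.null(n_pcs)) {
    n_pcs <- min(n_pcs, ncol(Xw), nrow(Xw) - 1L)
    Xw <- stats::prcomp(Xw, center = TRUE, scale. = FALSE,
                        rank. = n_pcs)$x
  }
  g <- build_knn_graph(Xw, k = k, metric = metric)
  a <- cluster_cells(g = g, X = Xw, method = cluster_method,
                     resolution = resolution, centers = centers, seed = seed)
  cg <- build_cluster_graph(g, a, aggregation = aggregation,
                            prune_frac = prune_frac)
  root_cluster <- select_root(cg, a, root, mode = root_mode,
                              annotations = annotations)
  comp <- cluster_components(cg)
  ids <- rownames(cg$W)
  nc <- cg$n
  roots <- character(0)
  t_closed <- t_refined <- stats::setNames(rep(NA_real_, nc), ids)
  ledgers <- list()
  lineage_blocks <- list()
  directed <- vector("list", max(comp))
  connectivity <- vector("list", max(comp))
  for (ci in seq_len(max(comp))) {
    sel <- which(comp == ci)
    sub_ids <- ids[sel]
    cfg <- walk_config(x = x, alpha = alpha, b = b, n_mcmc = n_mcmc,
                       max_steps = max_steps, seed = seed + 1000L * ci)
    if (length(sel) == 1L) {
      roots[ci] <- sub_ids
      t_closed[sub_ids] <- t_refined[sub_ids] <- 0
      next
    }
    sub <- structure(list(W = cg$W[sel, sel, drop = FALSE],
                          n = length(sel), sizes = cg$sizes[sel]),
                     class = "cluster_graph")
    croot <- if (as.character(root_cluster) %in% sub_ids)
      as.character(root_cluster) else component_anchor(sub)
    roots[ci] <- croot
    cache <- spectral_cache(sub, cfg)
    tc <- closed_form_hitting_times(cache, sub, croot)
    t_closed[sub_ids] <- tc
    # hitting times are in walk-step units of arbitrary magnitude; rescale to
    # [0, 10] per component before logistic biasing so adjacent-cluster time
    # differences land in the sensitive range of the logistic at b = 1
    dg <- forward_bias_edges(sub, rescale_bias(tc), cfg)
    tr <- mcmc_refine_pseudotime(dg, croot, cfg)
    t_refined[sub_ids] <- tr
    dg2 <- forward_bias_edges(sub, rescale_bias(tr), cfg)  # re-bias, refined
    directed[[ci]] <- dg2
    nc_metrics <- node_connectivity(dg2)
    connectivity[[ci]] <- nc_metrics
    ts <- withCallingHandlers(
      detect_terminal_states(nc_metrics, tr, croot),
      warning = function(w) {
        if (grepl("no terminal state", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    ledgers[[ci]] <- ts$ledger
    if (length(ts$terminals) > 0)
      lineage_blocks[[ci]] <- lineage_likelihoods(dg2, croot, ts, cfg)
  }
  terminals <- unlist(lapply(lineage_blocks, colnames), use.names = FALSE)
  L <- matrix(0, nc, length(terminals),
              dimnames = list(ids, terminals))
  for (blk in lineage_blocks) if (!is.null(blk))
    L[rownames(blk), colnames(blk)] <- blk
  pseudotime_cells <- project_to_cells(t_refined, g, a, n_smooth = n_smooth)
  lineage_cells <- if (length(terminals) > 0)
    project_to_cells(L, g, a, n_smooth = n_smooth)
  else matrix(0, nrow(X), 0, dimnames = list(rownames(X), NULL))
  structure(list(
    call = cl,
    knn = g, assignment = a, cluster_graph = cg,
    components = comp, roots = roots, root_cluster = root_cluster,
    pseudotime = data.frame(cluster_id = ids, t_closed = unname(t_closed),
                            t_refined = unname(t_refined), row.names = NULL),
    t_closed = t_closed, t_refined = t_refined,
    directed_graph = directed, connectivity = connectivity,
    terminals = terminals,
    terminal_ledger = if (length(ledgers) > 0) do.call(rbind, ledgers)
    else NULL,
    lineage_clusters = L,
    pseudotime_cells = pseudotime_cells, lineage_cells = lineage_cells,
    config = list(k = k, n_pcs = n_pcs, log1p = log1p,
                  cluster_method = cluster_method, resolution = resolution,
                  centers = centers, metric = metric,
                  aggregation = aggregation, prune_frac = prune_frac,
                  x = x, alpha = alpha, b = b, n_mcmc = n_mcmc,
                  max_steps = max_steps, n_smooth = n_smooth, seed = seed)),
    class = "trajwalk")
}

rescale_bias <- function(t, span = 10) {
  m <- max(t)
  if (m > 0) span * t / m else t
}

# anchor for a component without the user root: maximal-eccentricity node,
# ties broken by lowest cluster id
component_anchor <- function(cg) {
  ig <- igraph::graph_from_adjacency_matrix(cg$W > 0, mode = "undirected")
  ecc <- igraph::eccentricity(ig)
  rownames(cg$W)[order(-ecc, rownames(cg$W))][1]
}

#' @export
print.trajwalk <- function(x, ...) {
  cat("Lazy-teleporting random-walk trajectory fit\n")
  cat(sprintf("  %d cells, %d clusters, %d component(s)\n",
              x$knn$n, x$cluster_graph$n, max(x$components)))
  cat(sprintf("  root cluster: %s   terminal states: %s\n",
              x$root_cluster,
              if (length(x$terminals) > 0)
                paste(x$terminals, collapse = ", ") else "(none)"))
  invisible(x)
}

#' @export
summary.trajwalk <- function(object, ...) {
  cat("Lazy-teleporting random-walk trajectory fit\n\n")
  cat(sprintf("Cells: %d   Clusters: %d   Components: %d\n", object$knn$n,
              object$cluster_graph$n, max(object$components)))
  cat(sprintf("Walk: x = %g, alpha = %g, b = %g, n_mcmc = %d, seed = %d\n",
              object$config$x, object$config$alpha, object$config$b,
              object$config$n_mcmc, object$config$seed))
  cat(sprintf("Root cluster: %s (component anchors: %s)\n",
              object$root_cluster, paste(object$roots, collapse = ", ")))
  cat("\nCluster pseudotime:\n")
  print(object$pseudotime, digits = 4)
  if (length(object$terminals) > 0) {
    cat("\nTerminal states:", paste(object$terminals, collapse = ", "), "\n")
    cat("Mean lineage probability per terminal (cluster level):\n")
    print(round(colMeans(object$lineage_clusters), 3))
  } else cat("\nNo terminal states detected.\n")
  invisible(object)
}

#' Extract cell-level predictions from a trajectory fit
#'
#' @param object A `trajwalk` fit.
#' @param type `"pseudotime"` (per-cell refined pseudotime), `"lineage"`
#'   (cells x terminals probability matrix) or `"cluster"` (per-cell cluster
#'   id).
#' @param ... Unused.
#' @return Vector or matrix over cells.
#' @export
predict.trajwalk <- function(object, type = c("pseudotime", "lineage",
                                              "cluster"), ...) {
  type <- match.arg(type)
  switch(type,
         pseudotime = object$pseudotime_cells,
         lineage = object$lineage_cells,
         cluster = stats::setNames(object$assignment$labels,
                                   rownames(object$knn$adj)))
}

#' Plot the inferred cluster graph
#'
#' Nodes are placed by force-directed layout, sized by cluster population,
#' coloured by refined pseudotime (light early, dark late); terminal states
#' get a square symbol and the root a triangle.
#'
#' @param x A `trajwalk` fit.
#' @param ... Passed to [igraph::plot.igraph()].
#' @export
plot.trajwalk <- function(x, ...) {
  ig <- igraph::graph_from_adjacency_matrix(x$cluster_graph$W,
                                            mode = "undirected",
                                            weighted = TRUE)
  tt <- x$t_refined
  pal <- grDevices::colorRampPalette(c("#fee8c8", "#e34a33", "#7f0000"))(100)
  rel <- if (diff(range(tt)) > 0) (tt - min(tt)) / diff(range(tt))
         else rep(0, length(tt))
  shape <- ifelse(names(tt) %in% x$terminals, "square",
                  ifelse(names(tt) %in% x$roots, "csquare", "circle"))
  set.seed(x$config$seed)
  igraph::plot.igraph(
    ig, vertex.color = pal[pmax(1L, ceiling(rel * 100))],
    vertex.size = 8 + 20 * x$cluster_graph$sizes /
      max(x$cluster_graph$sizes),
    vertex.shape = shape,
    edge.width = 1 + 3 * igraph::E(ig)$weight / max(igraph::E(ig)$weight),
    ...)
  invisible(x)
}
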