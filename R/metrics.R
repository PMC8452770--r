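.im_gamma_cache <- new.env(parent = emptyenv())

as_unweighted_adj <- function(g) {
  if (inherits(g, "cluster_graph")) return((g$W > 0) * 1)
  if (inherits(g, "igraph"))
    g <- as.matrix(igraph::as_adjacency_matrix(g))
  A <- as.matrix(g)
  if (nrow(A) != ncol(A)) stop("adjacency matrix must be square")
  A <- (A != 0) * 1
  A <- pmax(A, t(A))   # undirected view
  diag(A) <- 0
  A
}

laplacian_frequencies <- function(A) {
  d <- rowSums(A)
  L <- diag(d, nrow(A)) - A
  sqrt(pmax(eigen(L, symmetric = TRUE, only.values = TRUE)$values, 0))
}

# Lorentzian-smoothed spectral density distance for fixed gamma
im_raw <- function(w1, w2, gamma) {
  K1 <- 1 / sum(pi / 2 + atan(w1 / gamma))
  K2 <- 1 / sum(pi / 2 + atan(w2 / gamma))
  rho <- function(w, wk, K)
    K * vapply(w, function(wi) sum(gamma / ((wi - wk)^2 + gamma^2)),
               numeric(1))
  f <- function(w) (rho(w, w1, K1) - rho(w, w2, K2))^2
  sqrt(stats::integrate(f, 0, Inf, subdivisions = 1000L,
                        rel.tol = 1e-8, stop.on.error = FALSE)$value)
}

im_gamma <- function(n) {
  key <- as.character(n)
  if (!is.null(.im_gamma_cache[[key]])) return(.im_gamma_cache[[key]])
  w_empty <- rep(0, n)
  w_full <- laplacian_frequencies(matrix(1, n, n) - diag(n))
  g <- stats::uniroot(function(lg) im_raw(w_empty, w_full, exp(lg)) - 1,
                      lower = log(1e-3), upper = log(10), tol = 1e-10)$root
  .im_gamma_cache[[key]] <- exp(g)
  exp(g)
}

#' Ipsen-Mikhailov spectral distance between two graphs
#'
#' Compares the Lorentzian-smoothed densities of the Laplacian vibrational
#' frequencies (square roots of Laplacian eigenvalues) of the undirected
#' views of two graphs. The Lorentzian half-width is calibrated per node
#' count so the distance between the empty and the complete graph is exactly
#' 1; graphs of unequal size are padded with isolated nodes.
#'
#' @param g1,g2 Adjacency matrices, `cluster_graph`s, or igraph objects.
#' @return Distance in `[0, 1]`; 0 for identical spectra; symmetric.
#' @export
im_distance <- function(g1, g2) {
  A1 <- as_unweighted_adj(g1)
  A2 <- as_unweighted_adj(g2)
  n <- max(nrow(A1), nrow(A2), 2L)
  pad <- function(A) {
    if (nrow(A) == n) return(A)
    B <- matrix(0, n, n)
    B[seq_len(nrow(A)), seq_len(ncol(A))] <- A
    B
  }
  gamma <- im_gamma(n)
  d <- im_raw(laplacian_frequencies(pad(A1)), laplacian_frequencies(pad(A2)),
              gamma)
  min(max(d, 0), 1)
}

#' Graph edit distance with unit costs
#'
#' Minimal number of node and edge insertions/deletions converting one
#' undirected graph into the other. With `matched = TRUE` the node names are
#' taken as a shared label space and the distance is the exact symmetric
#' difference of node and edge sets. Otherwise an exact branch-and-bound
#' search over node correspondences is run (graphs up to 12 nodes).
#'
#' @param g1,g2 Adjacency matrices (optionally named), `cluster_graph`s, or
#'   igraph objects.
#' @param matched Treat node names as a shared label space.
#' @return Nonnegative integer edit cost; 0 iff the graphs are isomorphic
#'   (matched: identical as labeled graphs).
#' @export
graph_edit_distance <- function(g1, g2, matched = FALSE) {
  A1 <- as_unweighted_adj(g1)
  A2 <- as_unweighted_adj(g2)
  if (matched) {
    if (is.null(rownames(A1)) || is.null(rownames(A2)))
      stop("matched = TRUE requires named nodes")
    v1 <- rownames(A1); v2 <- rownames(A2)
    edges <- function(A) {
      idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
      if (nrow(idx) == 0) return(character(0))
      paste(pmin(rownames(A)[idx[, 1]], rownames(A)[idx[, 2]]),
            pmax(rownames(A)[idx[, 1]], rownames(A)[idx[, 2]]), sep = "|")
    }
    e1 <- edges(A1); e2 <- edges(A2)
    return(length(setdiff(v1, v2)) + length(setdiff(v2, v1)) +
             length(setdiff(e1, e2)) + length(setdiff(e2, e1)))
  }
  if (nrow(A1) > nrow(A2)) { tmp <- A1; A1 <- A2; A2 <- tmp }
  n1 <- nrow(A1); n2 <- nrow(A2)
  if (n2 > 12L) stop("exact edit-distance search limited to <= 12 nodes; ",
                     "got ", n2)
  # pad A1 with isolated dummies; each dummy mapped to a real node costs 1
  Ap <- matrix(0, n2, n2)
  Ap[seq_len(n1), seq_len(n1)] <- A1
  best <- n2 - n1 + sum(Ap) / 2 + sum(A2) / 2   # delete-all upper bound
  used <- logical(n2)
  assign_node <- function(i, perm, cost) {
    if (cost >= best) return(invisible(NULL))
    if (i > n2) { best <<- cost; return(invisible(NULL)) }
    for (cand in seq_len(n2)[!used]) {
      add <- 0
      if (i > 1L)
        add <- sum(abs(Ap[i, seq_len(i - 1L)] - A2[cand, perm[seq_len(i - 1L)]]))
      if (cost + add < best) {
        used[cand] <<- TRUE
        perm[i] <- cand
        assign_node(i + 1L, perm, cost + add)
        used[cand] <<- FALSE
      }
    }
    invisible(NULL)
  }
  assign_node(1L, integer(n2), n2 - n1)
  as.integer(round(best))
}

normalize_edges <- function(edges) {
  if (is.null(edges) || NROW(edges) == 0) return(character(0))
  e <- as.data.frame(edges)
  a <- as.character(e[[1]]); b <- as.character(e[[2]])
  keep <- a != b
  unique(paste(pmin(a[keep], b[keep]), pmax(a[keep], b[keep]), sep = "|"))
}

f1_counts <- function(tp, fp, fn) {
  if (tp + fp + fn == 0) return(1)
  tp / (tp + 0.5 * (fp + fn))
}

#' Branch-level F1 score
#'
#' Harmonic mean of precision and recall over type-level undirected edges:
#' an edge of the reference network absent from the inferred network is a
#' false negative; an inferred edge absent from the reference is a false
#' positive. Self-edges (within one type) are ignored.
#'
#' @param inferred_edges,reference_edges Two-column data frames or matrices
#'   of endpoint type labels.
#' @return F1 in `[0, 1]`; 1 when both edge sets coincide.
#' @export
f1_branch <- function(inferred_edges, reference_edges) {
  ei <- normalize_edges(inferred_edges)
  er <- normalize_edges(reference_edges)
  f1_counts(length(intersect(ei, er)), length(setdiff(ei, er)),
            length(setdiff(er, ei)))
}

#' Temporal Pearson correlation
#'
#' Pearson correlation between inferred per-cell pseudotime and true sampling
#' time. Constant input is an error, not silently zero.
#'
#' @param t_inferred,t_true Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`.
#' @export
temporal_correlation <- function(t_inferred, t_true) {
  if (length(t_inferred) != length(t_true)) stop("length mismatch")
  if (length(t_inferred) < 3L) stop("need >= 3 cells")
  if (stats::sd(t_inferred) == 0 || stats::sd(t_true) == 0)
    stop("correlation undefined for constant pseudotime vector")
  stats::cor(t_inferred, t_true, method = "pearson")
}

#' Cell-fate F1 score
#'
#' `F1 = tp / (tp + 0.5 (fp + fn))` over type-level terminal-state sets: a
#' true positive is a predicted terminal type that is a reference cell fate,
#' a false positive a predicted terminal that is an intermediate state, and a
#' false negative a reference fate that was missed.
#'
#' @param predicted,reference Character vectors of terminal type labels;
#'   `reference` must be non-empty.
#' @return F1 in `[0, 1]`.
#' @export
f1_fate <- function(predicted, reference) {
  reference <- unique(as.character(reference))
  predicted <- unique(as.character(predicted))
  if (length(reference) == 0L) stop("empty reference terminal set")
  f1_counts(length(intersect(predicted, reference)),
            length(setdiff(predicted, reference)),
            length(setdiff(reference, predicted)))
}

#' Composite trajectory accuracy score
#'
#' Converts each metric to a percentage and averages: F1 scores and the
#' temporal correlation (clamped at 0) map to `100 * value`; the spectral
#' distance maps to `100 * (1 - im)`; the edit distance maps to
#' `100 * (1 - ged / ged_max)` where `ged_max` is the cost of editing both
#' graphs down to the empty graph. With `include_lineage = FALSE` the
#' cell-fate F1 is excluded and the mean runs over the remaining four.
#'
#' @param report Named list with `im`, `ged`, `ged_max`, `f1_branch`,
#'   `pearson_time` and (unless excluded) `f1_fate`.
#' @param include_lineage Include the cell-fate F1 (default TRUE).
#' @return Composite score in `[0, 100]`.
#' @export
composite_score <- function(report, include_lineage = TRUE) {
  need <- c("im", "ged", "ged_max", "f1_branch", "pearson_time")
  if (include_lineage) need <- c(need, "f1_fate")
  miss <- setdiff(need, names(report)[!vapply(report, is.null, logical(1))])
  if (length(miss) > 0) stop("missing component(s): ",
                             paste(miss, collapse = ", "))
  parts <- c(100 * (1 - report$im),
             100 * (1 - if (report$ged_max > 0)
               report$ged / report$ged_max else 0),
             100 * report$f1_branch,
             100 * max(report$pearson_time, 0),
             if (include_lineage) 100 * report$f1_fate)
  mean(parts)
}

#' Score a fitted trajectory against its reference
#'
#' Maps inferred clusters to reference types by majority vote (ties to the
#' lexicographically first type), contracts the cluster graph to a type-level
#' graph, and computes the five metrics plus the composite score. The edit
#' distance uses the shared type-label space (`matched = TRUE`).
#'
#' @param fit A `trajwalk` fit.
#' @param ref A `reference_trajectory`.
#' @return Object of class `score_report` (a named list): `im`, `ged`,
#'   `ged_max`, `f1_branch`, `pearson_time`, `f1_fate`, `composite`, plus the
#'   type mapping and graphs used.
#' @export
score_trajectory <- function(fit, ref) {
  types <- ref$cells$type
  type_of_cluster <- vapply(0:(fit$cluster_graph$n - 1L), function(c) {
    tab <- sort(table(types[fit$assignment$labels == c]), decreasing = TRUE)
    names(tab)[order(-tab, names(tab))][1]
  }, character(1))
  names(type_of_cluster) <- rownames(fit$cluster_graph$W)
  inferred <- contract_by_type(fit$cluster_graph$W, type_of_cluster)
  ref_adj <- milestone_adjacency(ref)
  idx <- which(fit$cluster_graph$W > 0 & upper.tri(fit$cluster_graph$W),
               arr.ind = TRUE)
  inf_edges <- data.frame(from = type_of_cluster[idx[, 1]],
                          to = type_of_cluster[idx[, 2]])
  ref_edges <- ref$edges[, c("from", "to")]
  report <- list(
    im = im_distance(inferred, ref_adj),
    ged = graph_edit_distance(inferred, ref_adj, matched = TRUE),
    ged_max = sum(inferred) / 2 + nrow(inferred) +
      sum(ref_adj) / 2 + nrow(ref_adj),
    f1_branch = f1_branch(inf_edges, ref_edges),
    pearson_time = temporal_correlation(fit$pseudotime_cells,
                                        ref$cells$true_time),
    f1_fate = if (length(ref$terminal_milestones) > 0)
      f1_fate(unique(type_of_cluster[fit$terminals]),
              ref$terminal_milestones) else NULL)
  report$composite <- composite_score(
    report, include_lineage = length(ref$terminal_milestones) > 0)
  report$type_of_cluster <- type_of_cluster
  report$inferred_type_graph <- inferred
  structure(report, class = c("score_report", "list"))
}

contract_by_type <- function(W, type_of_cluster) {
  types <- sort(unique(type_of_cluster))
  A <- matrix(0, length(types), length(types),
              dimnames = list(types, types))
  idx <- which(W > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    a <- type_of_cluster[idx[r, 1]]; b <- type_of_cluster[idx[r, 2]]
    if (a != b) A[a, b] <- 1
  }
  pmax(A, t(A))
}

milestone_adjacency <- function(ref) {
  ms <- ref$milestones
  A <- matrix(0, length(ms), length(ms), dimnames = list(ms, ms))
  A[cbind(ref$edges$from, ref$edges$to)] <- 1
  pmax(A, t(A))
}

#' @export
print.score_report <- function(x, ...) {
  cat("Trajectory score report\n")
  cat(sprintf("  IM distance      %.4f\n", x$im))
  cat(sprintf("  edit distance    %d (max %d)\n", x$ged,
              as.integer(x$ged_max)))
  cat(sprintf("  F1 branch        %.4f\n", x$f1_branch))
  cat(sprintf("  temporal Pearson %.4f\n", x$pearson_time))
  if (!is.null(x$f1_fate)) cat(sprintf("  F1 cell fate     %.4f\n", x$f1_fate))
  cat(sprintf("  composite        %.2f / 100\n", x$composite))
  invisible(x)
}
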