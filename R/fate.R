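#' Connectivity metrics of the directed cluster graph
#'
#' Metrics are computed on the unweighted hop-count view of the forward graph:
#' a directed edge i -> j is retained when its bias multiplier exceeds 0.5
#' (i.e. j is later in pseudotime), and both orientations are kept on ties.
#' Closeness is `C(q) = 1 / sum_r l(q, r)` over the nodes q reaches (`+Inf`
#' for dead ends that reach none — an empty distance sum, the leaf-like
#' extreme — and 0 for fully isolated nodes, flagged); betweenness is the Brandes sum over ordered source/
#' target pairs halved, so each unordered endpoint pair counts once;
#' out-degree is the total outgoing directed weight.
#'
#' @param dg A `directed_cluster_graph`.
#' @return Object of class `node_connectivity`: data frame with columns
#'   `node`, `out_degree`, `closeness`, `betweenness`, `reaches`.
#' @export
node_connectivity <- function(dg) {
  n <- nrow(dg$Wd)
  ids <- rownames(dg$Wd)
  forward <- (dg$W > 0) & (dg$mult >= 0.5)   # >= keeps both on exact ties
  ig <- igraph::graph_from_adjacency_matrix(forward, mode = "directed")
  dist <- igraph::distances(ig, mode = "out")    # unit hops
  reach <- rowSums(is.finite(dist)) - 1L
  sums <- rowSums(ifelse(is.finite(dist), dist, 0))
  # dead ends reach nothing: the distance sum is empty, so closeness is +Inf
  # (leaf-like); truly isolated nodes (no edges at all) get 0, flagged
  isolated <- rowSums(dg$W > 0) == 0
  closeness <- ifelse(reach > 0, 1 / sums, ifelse(isolated, 0, Inf))
  btw <- if (n > 1L) igraph::betweenness(ig, directed = TRUE) / 2 else 0
  out_degree <- rowSums(dg$Wd)
  forward_out <- rowSums((dg$W > 0) & (dg$mult > 0.5))  # strictly-later nbrs
  structure(data.frame(node = ids, out_degree = out_degree,
                       closeness = closeness, betweenness = btw,
                       reaches = reach, forward_out = forward_out,
                       row.names = NULL),
            class = c("node_connectivity", "data.frame"))
}

#' Detect terminal states by consensus vote
#'
#' A node is terminal iff it passes the pseudotime gate — refined pseudotime
#' at or above the component median AND no strictly-forward neighbour (a
#' local pseudotime maximum of the directed graph, i.e. a state with no
#' outgoing differentiation flow) — and wins at least `quorum` of the three
#' connectivity votes: out-degree at or below median, closeness strictly
#' above median, betweenness at or below median (directions configurable).
#' The root is never terminal. The per-node vote ledger is returned for
#' auditability.
#'
#' @param nc A `node_connectivity`.
#' @param t_refined Named refined pseudotime over the same nodes.
#' @param root Root cluster id.
#' @param quorum Votes needed among the three connectivity criteria
#'   (default all 3).
#' @param directions Named character vector over
#'   `c(out_degree, closeness, betweenness)` with values `"below"`/`"above"`.
#' @return Object of class `terminal_states`: list with `terminals`
#'   (character ids) and `ledger` (data frame of per-node votes).
#' @export
detect_terminal_states <- function(nc, t_refined, root, quorum = 3L,
                                   directions = c(out_degree = "below",
                                                  closeness = "above",
                                                  betweenness = "below")) {
  ids <- nc$node
  if (!all(ids %in% names(t_refined)))
    stop("pseudotime and connectivity metrics cover different node sets")
  tt <- t_refined[ids]
  # "below" is non-strict (metrics such as betweenness are frequently 0 and
  # tie with the median); "above" is strict so uniform graphs vote nobody in
  vote <- function(v, dir) {
    if (dir == "below") v <= stats::median(v) else v > stats::median(v)
  }
  v_out <- vote(nc$out_degree, directions[["out_degree"]])
  v_clo <- vote(nc$closeness, directions[["closeness"]])
  v_btw <- vote(nc$betweenness, directions[["betweenness"]])
  local_max <- if ("forward_out" %in% names(nc)) nc$forward_out == 0 else TRUE
  gate <- tt >= stats::median(tt) & local_max
  votes <- v_out + v_clo + v_btw
  term <- gate & votes >= quorum & ids != as.character(root)
  ledger <- data.frame(node = ids, t_refined = unname(tt),
                       local_max = local_max,
                       pseudotime_gate = tt >= stats::median(tt),
                       out_degree_vote = v_out,
                       closeness_vote = v_clo, betweenness_vote = v_btw,
                       votes = votes, terminal = term, row.names = NULL)
  if (!any(term))
    warning("no terminal state detected (degenerate topology, e.g. a pure ",
            "cycle or uniform pseudotime)")
  structure(list(terminals = ids[term], ledger = ledger),
            class = "terminal_states")
}

#' Lineage likelihoods by walk visitation frequency
#'
#' Simulates lazy-teleporting walks from the root on the forward-biased
#' graph; a walk ends on first arrival at any terminal state, and is
#' successful for that terminal. The likelihood that cluster i belongs to the
#' lineage of terminal j is the number of visits to i during j-successful
#' walks divided by the visits to i over all walks.
#'
#' @param dg A `directed_cluster_graph`.
#' @param root Root cluster id.
#' @param terminals A `terminal_states` object or character vector of ids.
#' @param cfg A `walk_config`.
#' @return Matrix (clusters x terminals) of probabilities in `[0, 1]`.
#' @export
lineage_likelihoods <- function(dg, root, terminals, cfg = walk_config()) {
  term <- if (inherits(terminals, "terminal_states")) terminals$terminals
          else as.character(terminals)
  ids <- rownames(dg$Wd)
  if (length(term) == 0L)
    return(matrix(0, nrow(dg$Wd), 0, dimnames = list(ids, NULL)))
  sim <- simulate_walks(dg, root, cfg, terminals = term,
                        stop_at_terminal = TRUE, seed_offset = 2L)
  tot <- colSums(sim$visits)
  L <- sapply(term, function(j) {
    ok <- sim$end_state == (match(j, ids) - 1L)
    if (!any(ok)) return(rep(0, length(ids)))
    colSums(sim$visits[ok, , drop = FALSE]) / pmax(tot, 1e-300)
  })
  L <- matrix(L, nrow = length(ids), dimnames = list(ids, term))
  unreached <- term[colSums(L) == 0]
  if (length(unreached) > 0L)
    warning("terminal state(s) never reached by any walk: ",
            paste(unreached, collapse = ", "))
  L[tot == 0, ] <- 0
  pmin(pmax(L, 0), 1)
}

#' Project cluster-level values onto single cells
#'
#' One smoothing pass sets each cell to the affinity-weighted mean, over its
#' KNN neighbours, of the neighbours' cluster values; further passes smooth
#' the resulting per-cell values on the same graph. Values stay inside the
#' range of the cluster-level input. Cells without neighbours keep their own
#' cluster's value.
#'
#' @param cluster_values Named per-cluster vector, or a clusters x k matrix
#'   (e.g. a lineage matrix) with cluster ids as rownames.
#' @param g An `sc_knn_graph`.
#' @param a A `cluster_assignment`.
#' @param n_smooth Number of smoothing passes (>= 1).
#' @return Per-cell vector or cells x k matrix.
#' @export
project_to_cells <- function(cluster_values, g, a, n_smooth = 1L) {
  vec_in <- is.null(dim(cluster_values))
  V <- if (vec_in) matrix(cluster_values, ncol = 1,
                          dimnames = list(names(cluster_values), NULL))
       else as.matrix(cluster_values)
  key <- as.character(a$labels)
  if (!all(key %in% rownames(V))) stop("cluster values do not cover all clusters")
  own <- V[key, , drop = FALSE]          # cells x k: own-cluster value
  rs <- Matrix::rowSums(g$adj)
  Tm <- g$adj / ifelse(rs > 0, rs, 1)
  iso <- rs == 0
  out <- own
  for (i in seq_len(n_smooth)) {
    sm <- as.matrix(Tm %*% out)
    sm[iso, ] <- out[iso, , drop = FALSE]  # isolated cells keep their value
    out <- sm
  }
  # clamp rounding epsilon so the hull contract is exact per column
  for (j in seq_len(ncol(out)))
    out[, j] <- pmin(pmax(out[, j], min(V[, j])), max(V[, j]))
  rownames(out) <- rownames(g$adj)
  if (vec_in) stats::setNames(out[, 1], rownames(out)) else out
}
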