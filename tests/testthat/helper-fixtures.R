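# fixtures are built in code at test time

# two well-separated Gaussian blobs (sigma = 0.1, centers 10 apart)
make_blobs <- function(n_per = 50, sd = 0.1, sep = 10, seed = 11) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * 2, 0, sd), ncol = 2),
             matrix(rnorm(n_per * 2, sep, sd), ncol = 2))
  rownames(X) <- paste0("c", seq_len(2 * n_per))
  colnames(X) <- c("f1", "f2")
  list(X = X, label = rep(0:1, each = n_per))
}

# random connected weighted graph as a cluster_graph
random_connected_graph <- function(n, seed) {
  set.seed(seed)
  repeat {
    W <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (runif(1) < 0.6) W[i, j] <- W[j, i] <- runif(1, 0.2, 2)
    ig <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
    if (igraph::is_connected(ig) && all(rowSums(W) > 0)) break
  }
  dimnames(W) <- list(as.character(seq_len(n) - 1L),
                      as.character(seq_len(n) - 1L))
  structure(list(W = W, n = n, sizes = rep(1L, n)), class = "cluster_graph")
}

# independent oracle: expected first-hitting times of a Markov chain K,
# target r absorbed, (I - Q) h = 1
hitting_time_oracle <- function(K, target) {
  n <- nrow(K)
  idx <- setdiff(seq_len(n), target)
  h <- rep(0, n)
  h[idx] <- solve(diag(n - 1L) - K[idx, idx, drop = FALSE], rep(1, n - 1L))
  h
}

# directed cluster graph built verbatim from a directed weight matrix
manual_directed_graph <- function(Wd, t = NULL) {
  W <- pmax(Wd, t(Wd))
  mult <- ifelse(W > 0, Wd / W, 0)
  if (is.null(t)) t <- stats::setNames(rep(0, nrow(Wd)), rownames(Wd))
  structure(list(Wd = Wd, mult = mult, W = W, t = t, b = 1),
            class = "directed_cluster_graph")
}

# small undirected path A-B-C as an adjacency matrix with both orientations
path3_directed <- function() {
  ids <- c("A", "B", "C")
  Wd <- matrix(0, 3, 3, dimnames = list(ids, ids))
  Wd["A", "B"] <- Wd["B", "A"] <- Wd["B", "C"] <- Wd["C", "B"] <- 1
  manual_directed_graph(Wd)
}

# exhaustive unlabeled graph edit distance over all node correspondences
ged_oracle <- function(A1, A2) {
  A1 <- (A1 != 0) * 1; A2 <- (A2 != 0) * 1
  if (nrow(A1) > nrow(A2)) { tmp <- A1; A1 <- A2; A2 <- tmp }
  n1 <- nrow(A1); n2 <- nrow(A2)
  Ap <- matrix(0, n2, n2)
  Ap[seq_len(n1), seq_len(n1)] <- A1
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- Inf
  for (p in perms(seq_len(n2))) {
    cost <- (n2 - n1) + sum(abs(Ap - A2[p, p])) / 2
    best <- min(best, cost)
  }
  as.integer(best)
}

fit_small_bifurcation <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    sim <- simulate_trajectory(topology_spec("bifurcation", n_cells = 300,
                                             n_features = 150, seed = 5))
    fit <- trajwalk(sim$X, root = "M1", root_mode = "group_label",
                    annotations = sim$ref$cells$type, k = 10, n_pcs = 5,
                    log1p = TRUE, n_mcmc = 300, seed = 2)
    cache <<- list(sim = sim, fit = fit)
    cache
  }
})
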