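test_that("knn graph finds the expected neighbours on collinear points", {
  X <- matrix(c(0, 1, 10), ncol = 1,
              dimnames = list(c("a", "b", "c"), "f"))
  g <- build_knn_graph(X, k = 1)
  # before symmetrisation: b -> a and c -> b; union keeps both plus a -> b
  expect_gt(g$adj["b", "a"], 0)
  expect_gt(g$adj["c", "b"], 0)
  expect_equal(g$adj["c", "a"], 0)
})

test_that("symmetrised adjacency equals its transpose and has no self-loops", {
  set.seed(21)
  for (i in 1:5) {
    X <- matrix(rnorm(40 * 3), 40, 3)
    g <- build_knn_graph(X, k = sample(2:8, 1),
                         metric = sample(c("euclidean", "cosine"), 1))
    expect_equal(as.matrix(g$adj), t(as.matrix(g$adj)))
    expect_true(all(Matrix::diag(g$adj) == 0))
    expect_true(all(g$adj@x >= 0))
  }
})

test_that("well-separated blobs get no cross-blob edges", {
  b <- make_blobs()
  g <- build_knn_graph(b$X, k = 5)
  A <- as.matrix(g$adj)
  expect_equal(sum(A[b$label == 0, b$label == 1]), 0)
})

test_that("knn parameter and data errors are raised", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(build_knn_graph(X, k = 0), "k must")
  expect_error(build_knn_graph(X, k = 10), "k must")
  X[1, 1] <- NA
  expect_error(build_knn_graph(X, k = 2), "finite")
})

test_that("kmeans separates trivially separable values exactly", {
  X <- matrix(c(0, 0, 10, 10), ncol = 1,
              dimnames = list(paste0("c", 1:4), "f"))
  a <- cluster_cells(X = X, method = "kmeans", centers = 2, seed = 1)
  expect_equal(a$n_clusters, 2L)
  expect_identical(a$labels[1], a$labels[2])
  expect_identical(a$labels[3], a$labels[4])
  expect_false(a$labels[1] == a$labels[3])
  expect_setequal(unique(a$labels), 0:1)
})

test_that("community detection never merges disconnected components and
           recovers blob identity", {
  b <- make_blobs()
  g <- build_knn_graph(b$X, k = 5)
  a <- cluster_cells(g = g, seed = 3)
  # no cluster spans the two graph components
  tab <- table(a$labels, b$label)
  expect_true(all(rowSums(tab > 0) == 1))
  # blob identity recovered for 100% of cells after merging within-blob labels
  blob_of_cluster <- apply(tab, 1, which.max)
  expect_equal(unname(blob_of_cluster[as.character(a$labels)]) - 1L,
               b$label)
})

test_that("clustering is stable under cell permutation (fixed seed)", {
  b <- make_blobs()
  perm <- sample(seq_len(nrow(b$X)))
  g1 <- build_knn_graph(b$X, k = 5)
  g2 <- build_knn_graph(b$X[perm, ], k = 5)
  a1 <- cluster_cells(g = g1, seed = 7)
  a2 <- cluster_cells(g = g2, seed = 7)
  # the partitions coincide as set systems
  expect_equal(length(unique(paste(a1$labels[perm], a2$labels))),
               a1$n_clusters)
})

test_that("cluster graph aggregation is conservative and symmetric", {
  b <- make_blobs()
  g <- build_knn_graph(b$X, k = 5)
  a <- cluster_cells(g = g, seed = 3)
  cg <- build_cluster_graph(g, a)
  expect_equal(cg$W, t(cg$W))
  expect_true(all(diag(cg$W) == 0))
  # conservation: total inter-cluster cluster-edge weight equals the total
  # inter-cluster single-cell edge weight
  A <- as.matrix(g$adj)
  inter <- sum(A[outer(a$labels, a$labels, "!=")]) / 2
  expect_equal(sum(cg$W[upper.tri(cg$W)]), inter, tolerance = 1e-12)
  # components of the cluster graph mirror components of the sc graph
  expect_equal(max(cluster_components(cg)), 2L)
})

test_that("degenerate aggregations behave: one cluster, counted edges", {
  b <- make_blobs(n_per = 10)
  g <- build_knn_graph(b$X, k = 3)
  one <- structure(list(labels = rep(0L, g$n), n_clusters = 1L),
                   class = "cluster_assignment")
  cg1 <- build_cluster_graph(g, one)
  expect_equal(cg1$n, 1L)
  expect_equal(sum(cg1$W), 0)
  # 2 clusters joined by exactly 3 unit-weight edges -> w_12 = 3
  adj <- Matrix::sparseMatrix(i = c(1, 2, 3), j = c(4, 5, 6), x = 1,
                              dims = c(6, 6), symmetric = FALSE)
  adj <- adj + Matrix::t(adj)
  dimnames(adj) <- list(paste0("c", 1:6), paste0("c", 1:6))
  gg <- structure(list(adj = adj, k = 1L, metric = "euclidean", n = 6L),
                  class = "sc_knn_graph")
  aa <- structure(list(labels = rep(0:1, each = 3L), n_clusters = 2L),
                  class = "cluster_assignment")
  cg2 <- build_cluster_graph(gg, aa)
  expect_equal(cg2$W["0", "1"], 3)
})

test_that("pruning drops weak edges but never disconnects a component", {
  cg <- random_connected_graph(8, seed = 2)
  cg$W[1, 2] <- cg$W[2, 1] <- 1e-4       # one spurious weak edge
  g <- structure(list(W = cg$W, n = 8L, sizes = rep(1L, 8)),
                 class = "cluster_graph")
  pruned <- prune_weak_edges(g$W, frac = 0.3)
  expect_true(pruned[1, 2] == 0 || igraph::is_connected(
    igraph::graph_from_adjacency_matrix(pruned > 0, mode = "undirected")))
  expect_true(igraph::is_connected(
    igraph::graph_from_adjacency_matrix(pruned > 0, mode = "undirected")))
})

test_that("root selection handles all three modes and tie-breaks", {
  b <- make_blobs()
  g <- build_knn_graph(b$X, k = 5)
  a <- cluster_cells(g = g, seed = 3)
  cg <- build_cluster_graph(g, a)
  expect_equal(select_root(cg, a, 7, mode = "cell_index"), a$labels[7])
  expect_equal(select_root(cg, a, a$labels[60], mode = "cluster_id"),
               a$labels[60])
  ann <- ifelse(b$label == 0, "HSC", "other")
  r <- select_root(cg, a, "HSC", mode = "group_label", annotations = ann)
  expect_true(all(b$label[a$labels == r] == 0))
  expect_error(select_root(cg, a, "absent", mode = "group_label",
                           annotations = ann), "not present")
  # tie on majority: higher degree + lower betweenness wins (5-node toy:
  # path 0-1-2-3-4 plus edge 1-2 strengthened; candidates 1 and 3)
  W <- matrix(0, 5, 5, dimnames = rep(list(as.character(0:4)), 2))
  W[cbind(1:4, 2:5)] <- W[cbind(2:5, 1:4)] <- 1
  W["1", "2"] <- W["2", "1"] <- 3
  cg5 <- structure(list(W = W, n = 5L, sizes = rep(2L, 5)),
                   class = "cluster_graph")
  a5 <- structure(list(labels = rep(0:4, each = 2L), n_clusters = 5L),
                  class = "cluster_assignment")
  ann5 <- rep(c("x", "y", "x", "x", "y"), each = 2L)
  # clusters 0, 2, 3 are pure "x"; cluster 2 has the highest degree but high
  # betweenness; endpoint 0 has low betweenness but low degree
  r5 <- select_root(cg5, a5, "x", mode = "group_label", annotations = ann5)
  deg <- rowSums(W)
  btw <- igraph::betweenness(igraph::graph_from_adjacency_matrix(
    W > 0, mode = "undirected"))
  cand <- c("0", "2", "3")
  score <- rank(-deg[cand]) + rank(btw[cand])
  expect_equal(as.character(r5), cand[which.min(score)])
})
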