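two_node_graph <- function() {
  W <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = rep(list(c("0", "1")), 2))
  structure(list(W = W, n = 2L, sizes = c(1L, 1L)), class = "cluster_graph")
}

test_that("transition operators collapse correctly in limiting cases", {
  cg <- two_node_graph()
  ops <- transition_operators(cg, walk_config(x = 1, alpha = 1))
  expect_equal(unname(ops$P), matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(ops$Zprime, ops$P)   # x = 1, alpha = 1 collapse
  # triangle, x = 0.5: lazy diagonal 0.5, off-diagonal 0.25
  W <- matrix(1, 3, 3, dimnames = rep(list(as.character(0:2)), 2))
  diag(W) <- 0
  tri <- structure(list(W = W, n = 3L, sizes = rep(1L, 3)),
                   class = "cluster_graph")
  ops3 <- transition_operators(tri, walk_config(x = 0.5, alpha = 0.9))
  expect_equal(unname(diag(ops3$Z)), rep(0.5, 3))
  expect_equal(unname(ops3$Z[1, 2]), 0.25)
  for (m in ops3) {
    expect_equal(unname(rowSums(m)), rep(1, 3), tolerance = 1e-12)
    expect_true(all(m >= 0))
  }
  expect_true(all(ops3$Zprime > 0))  # teleportation makes it strictly positive
})

test_that("spectral cache matches hand eigendecomposition on the 2-node graph", {
  cg <- two_node_graph()
  cfg <- walk_config(x = 0.9, alpha = 0.95)
  sc <- spectral_cache(cg, cfg)
  expect_equal(sort(sc$eta), c(0, 2), tolerance = 1e-12)
  expect_equal(sc$beta, 2 * (1 - 0.95) / (2 - 0.95))
  # analytic eigenpairs of the 2-node normalized Laplacian
  phi1 <- c(1, 1) / sqrt(2); phi2 <- c(1, -1) / sqrt(2)
  R_hand <- outer(phi1, phi1) / sc$beta +
    outer(phi2, phi2) / (sc$beta + 2 * 0.9 * (1 - sc$beta) * 2)
  expect_equal(unname(sc$R), R_hand, tolerance = 1e-12)
  expect_equal(sc$R, t(sc$R))
})

test_that("beta formula endpoints and degenerate parameters", {
  expect_equal(2 * (1 - 1) / (2 - 1), 0)   # documented formula at alpha = 1
  cg <- two_node_graph()
  sc0 <- spectral_cache(cg, walk_config(x = 0.5, alpha = 1e-12))
  expect_equal(sc0$beta, 1, tolerance = 1e-11)   # alpha -> 0 gives beta -> 1
  expect_error(spectral_cache(cg, walk_config(x = 0.5, alpha = 1)),
               "degenerate")
})

test_that("closed-form hitting times match the Z' linear-system oracle", {
  cfg <- walk_config(x = 0.9, alpha = 0.95)
  cg <- two_node_graph()
  sc <- spectral_cache(cg, cfg)
  h <- closed_form_hitting_times(sc, cg, "0")
  expect_equal(unname(h["0"]), 0)
  ops <- transition_operators(cg, cfg)
  expect_equal(unname(h["1"]), hitting_time_oracle(ops$Zprime, 2)[1],
               tolerance = 1e-10)
  expect_error(closed_form_hitting_times(sc, cg, "9"), "root")
})

test_that("hitting times converge to classical random-walk times as
           alpha, x -> 1 (path graph)", {
  n <- 5
  W <- matrix(0, n, n, dimnames = rep(list(as.character(0:(n - 1))), 2))
  W[cbind(1:(n - 1), 2:n)] <- W[cbind(2:n, 1:(n - 1))] <- 1
  cg <- structure(list(W = W, n = n, sizes = rep(1L, n)),
                  class = "cluster_graph")
  cfg <- walk_config(x = 1 - 1e-9, alpha = 1 - 1e-9)
  h <- closed_form_hitting_times(spectral_cache(cg, cfg), cg, "0")
  # classical hitting time from the end of a path: h(0 -> k) = k^2
  expect_equal(unname(h), (0:(n - 1))^2, tolerance = 1e-5)
})

test_that("forward biasing satisfies the logistic-symmetry contract", {
  cg <- random_connected_graph(6, seed = 4)
  cg$W["1", "2"] <- cg$W["2", "1"] <- 0.7   # pin the edges the checks use
  cg$W["4", "5"] <- cg$W["5", "4"] <- 1.1
  t <- setNames(c(0, 1, 1, 2, 5, 5 + log(3)), rownames(cg$W))
  dg <- forward_bias_edges(cg, t, walk_config(b = 1))
  # equal pseudotime -> both orientations 0.5
  expect_equal(dg$mult["1", "2"], 0.5)
  # multipliers of the two orientations sum to 1 on every edge
  on_edge <- cg$W > 0
  expect_equal((dg$mult + t(dg$mult))[on_edge],
               rep(1, sum(on_edge)), tolerance = 1e-12)
  # magnitude preserved as multiplicand
  expect_equal(dg$Wd[on_edge], (cg$W * dg$mult)[on_edge])
  # delta t = ln 3 forward -> multiplier 0.75
  expect_equal(dg$mult["4", "5"], 0.75)
  expect_error(forward_bias_edges(cg, t[-1], walk_config()), "pseudotime")
})

test_that("forward weights dominate reverse on a monotone path", {
  n <- 5
  W <- matrix(0, n, n, dimnames = rep(list(as.character(0:(n - 1))), 2))
  W[cbind(1:(n - 1), 2:n)] <- W[cbind(2:n, 1:(n - 1))] <- 1
  cg <- structure(list(W = W, n = n, sizes = rep(1L, n)),
                  class = "cluster_graph")
  dg <- forward_bias_edges(cg, setNames(0:4, rownames(W)), walk_config())
  for (i in 1:(n - 1))
    expect_gt(dg$Wd[as.character(i - 1), as.character(i)],
              dg$Wd[as.character(i), as.character(i - 1)])
})

test_that("refined pseudotime is exact on a deterministic chain", {
  ids <- c("r", "A", "B")
  Wd <- matrix(0, 3, 3, dimnames = list(ids, ids))
  Wd["r", "A"] <- 1; Wd["A", "B"] <- 1
  dg <- manual_directed_graph(Wd)
  tr <- mcmc_refine_pseudotime(dg, "r", walk_config(x = 1, alpha = 1,
                                                    n_mcmc = 50, seed = 9))
  expect_equal(unname(tr), c(0, 1, 2))
})

test_that("refined pseudotime increases with depth on a balanced binary tree", {
  ids <- c("r", "a", "b", "aa", "ab", "ba", "bb")
  Wd <- matrix(0, 7, 7, dimnames = list(ids, ids))
  Wd["r", "a"] <- Wd["r", "b"] <- 1
  Wd["a", "aa"] <- Wd["a", "ab"] <- 1
  Wd["b", "ba"] <- Wd["b", "bb"] <- 1
  dg <- manual_directed_graph(Wd)
  tr <- mcmc_refine_pseudotime(dg, "r", walk_config(x = 1, alpha = 1,
                                                    n_mcmc = 10000, seed = 3))
  expect_equal(unname(tr["r"]), 0)
  expect_true(all(tr[c("a", "b")] >= 1))       # depth-d node needs >= d steps
  expect_true(all(tr[c("aa", "ab", "ba", "bb")] >= 2))
  expect_gt(min(tr[c("aa", "ab", "ba", "bb")]), max(tr[c("a", "b")]))
})

test_that("refinement is reproducible and warns on unreachable nodes", {
  cg <- random_connected_graph(7, seed = 6)
  t <- setNames(seq(0, 3, length.out = 7), rownames(cg$W))
  dg <- forward_bias_edges(cg, t, walk_config())
  cfg <- walk_config(n_mcmc = 200, seed = 5)
  expect_identical(mcmc_refine_pseudotime(dg, "0", cfg),
                   mcmc_refine_pseudotime(dg, "0", cfg))
  # strictly forward chain with x = 1, alpha = 1: nodes before the root are
  # unreachable and must fall back with a warning
  ids <- c("p", "r", "q")
  Wd <- matrix(0, 3, 3, dimnames = list(ids, ids))
  Wd["p", "r"] <- 1; Wd["r", "q"] <- 1
  dgc <- manual_directed_graph(Wd, t = setNames(c(0, 1, 2), ids))
  expect_warning(
    tr <- mcmc_refine_pseudotime(dgc, "r", walk_config(x = 1, alpha = 1,
                                                       n_mcmc = 20, seed = 1)),
    "never visited")
  expect_equal(unname(tr["r"]), 0)
  expect_true(is.finite(tr["p"]))
})

test_that("refined ordering is isomorphism-stable in expectation", {
  cg <- random_connected_graph(6, seed = 8)
  t <- setNames(seq(0, 4, length.out = 6), rownames(cg$W))
  dg <- forward_bias_edges(cg, t, walk_config())
  perm <- c(3L, 1L, 6L, 2L, 5L, 4L)
  Wp <- cg$W[perm, perm]
  dimnames(Wp) <- dimnames(cg$W)   # relabel nodes
  cgp <- structure(list(W = Wp, n = 6L, sizes = rep(1L, 6)),
                   class = "cluster_graph")
  tp <- setNames(t[perm], rownames(cg$W))
  dgp <- forward_bias_edges(cgp, tp, walk_config())
  avg <- function(d, root) {
    Reduce(`+`, lapply(1:4, function(s)
      mcmc_refine_pseudotime(d, root, walk_config(n_mcmc = 1500,
                                                  seed = s)))) / 4
  }
  root_orig <- "1"
  root_perm <- rownames(cg$W)[which(perm == as.integer(root_orig) + 1L)]
  a1 <- avg(dg, root_orig)
  a2 <- avg(dgp, root_perm)
  # permuted run, mapped back, matches within Monte-Carlo error
  expect_equal(unname(a2[match(seq_along(perm), perm)]), unname(a1),
               tolerance = 0.25)
})
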