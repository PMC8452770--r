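#' Configuration of the lazy-teleporting random walk
#'
#' @param x Retention probability in (0, 1]: at a non-teleport step the walker
#'   moves with probability `x` and stays (is lazy) with probability `1 - x`.
#' @param alpha Teleport retention probability in (0, 1]: each step teleports
#'   uniformly with probability `1 - alpha`.
#' @param b Logistic growth factor of the forward-bias function (default 1).
#' @param n_mcmc Number of simulated walks.
#' @param max_steps Step cap per walk; `NULL` means `1000 * n_clusters`,
#'   resolved where the walk runs.
#' @param seed Integer seed threaded through all stochastic stages.
#' @return Object of class `walk_config`.
#' @export
walk_config <- function(x = 0.95, alpha = 0.99, b = 1, n_mcmc = 1000L,
                        max_steps = NULL, seed = 42L) {
  if (x <= 0 || x > 1) stop("x must be in (0, 1]")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (b <= 0) stop("b must be > 0")
  if (n_mcmc < 1L) stop("n_mcmc must be >= 1")
  if (!is.null(max_steps) && max_steps < 1L) stop("max_steps must be >= 1")
  structure(list(x = x, alpha = alpha, b = b, n_mcmc = as.integer(n_mcmc),
                 max_steps = max_steps, seed = as.integer(seed)),
            class = "walk_config")
}

#' Transition operators of the walk
#'
#' Returns the row-stochastic transition matrix `P = D^{-1} W` of the plain
#' random walk, the lazy operator `Z = xP + (1-x)I`, and the lazy-teleporting
#' operator `Zprime = alpha Z + (1-alpha) J/n`.
#'
#' @param cg A `cluster_graph`.
#' @param cfg A `walk_config`.
#' @return List with matrices `P`, `Z`, `Zprime` (all rows sum to 1).
#' @export
transition_operators <- function(cg, cfg = walk_config()) {
  W <- cg$W
  n <- nrow(W)
  d <- rowSums(W)
  if (n > 1L && any(d == 0) && any(W > 0))
    stop("zero-degree node in a multi-node component: cluster(s) ",
         paste(rownames(W)[d == 0], collapse = ", "))
  P <- if (all(d == 0)) diag(n) else W / d   # isolated/trivial: identity
  Z <- cfg$x * P + (1 - cfg$x) * diag(n)
  Zp <- cfg$alpha * Z + (1 - cfg$alpha) * matrix(1 / n, n, n)
  dimnames(P) <- dimnames(Z) <- dimnames(Zp) <- dimnames(W)
  list(P = P, Z = Z, Zprime = Zp)
}

#' Spectral cache for closed-form hitting times
#'
#' Eigendecomposes the symmetric normalized Laplacian
#' `L = I - D^{-1/2} W D^{-1/2}` of a connected cluster graph and assembles
#' the resolvent `R = sum_m Phi_m Phi_m^T / (beta + 2x(1-beta) eta_m)` with
#' `beta = 2(1-alpha)/(2-alpha)`, retaining every eigenpair (the dimension is
#' the number of clusters, so no truncation is needed).
#'
#' @param cg A connected `cluster_graph` with >= 2 nodes.
#' @param cfg A `walk_config` with `alpha < 1`.
#' @return Object of class `spectral_cache`: `Phi`, `eta`, `beta`, `R`, and
#'   `M = D^{-1/2} R D^{-1/2}` plus the degree vector `d`.
#' @export
spectral_cache <- function(cg, cfg = walk_config()) {
  W <- cg$W
  n <- nrow(W)
  d <- rowSums(W)
  if (n < 2L) stop("spectral cache needs >= 2 nodes")
  if (any(d == 0)) stop("zero-degree node in component: cluster(s) ",
                        paste(rownames(W)[d == 0], collapse = ", "))
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    W > 0, mode = "undirected"))
  if (comp$no > 1L) stop("graph is disconnected; build one cache per component")
  Dm <- 1 / sqrt(d)
  L <- diag(n) - (Dm * W) * rep(Dm, each = n)   # D^-1/2 W D^-1/2 conjugation
  L <- (L + t(L)) / 2
  ee <- eigen(L, symmetric = TRUE)
  beta <- 2 * (1 - cfg$alpha) / (2 - cfg$alpha)
  den <- beta + 2 * cfg$x * (1 - beta) * ee$values
  if (any(den <= 1e-14))
    stop(sprintf(paste0("degenerate walk parameters: denominator ",
                        "beta + 2x(1-beta)eta is ~0 (alpha=%g, x=%g, ",
                        "eta=%g); need alpha < 1"),
                 cfg$alpha, cfg$x, ee$values[which.min(den)]))
  R <- ee$vectors %*% (t(ee$vectors) / den)
  M <- (Dm * R) * rep(Dm, each = n)
  dimnames(M) <- dimnames(R) <- dimnames(W)
  structure(list(Phi = ee$vectors, eta = ee$values, beta = beta, R = R,
                 M = M, d = d, x = cfg$x, alpha = cfg$alpha),
            class = "spectral_cache")
}

#' Closed-form expected hitting times from the root
#'
#' Pseudotime of node r is the expected number of steps for the
#' lazy-teleporting walk started at the root to first reach r. The spectral
#' difference `beta (e_r - e_root)^T M e_r` determines the hitting time up to
#' a per-target scale; the exact scale follows from the absorbed linear system
#' of the chain and equals `n / ((1-alpha) beta sum_q M[q, r])`, giving
#' `h(root -> r) = n (M[r,r] - M[root,r]) / ((1-alpha) sum_q M[q,r])` in walk
#' steps (derivation in the methods vignette). Teleport arrivals count as
#' hits.
#'
#' @param cache A `spectral_cache`.
#' @param cg The `cluster_graph` the cache was built from.
#' @param root Root cluster id (matched against cluster graph node names).
#' @return Named numeric vector of hitting times; 0 at the root.
#' @export
closed_form_hitting_times <- function(cache, cg, root) {
  M <- cache$M
  q0 <- match(as.character(root), rownames(M))
  if (is.na(q0)) stop("root cluster not found: ", root)
  cs <- colSums(M)
  h <- nrow(M) * (diag(M) - M[q0, ]) / ((1 - cache$alpha) * cs)
  h[q0] <- 0
  h
}

#' Forward-bias edges by pseudotime
#'
#' Each undirected edge {i, j} is split into two directed edges with
#' multipliers `f(i -> j) = 1 / (1 + exp(-b (t_j - t_i)))` and its complement,
#' so the orientation toward the later-pseudotime endpoint gets the larger
#' share and the two multipliers sum to 1. Directed weight is
#' `w_ij * f(i -> j)`.
#'
#' @param cg A `cluster_graph`.
#' @param t Named pseudotime vector covering all nodes of `cg`.
#' @param cfg A `walk_config` (uses `b`).
#' @return Object of class `directed_cluster_graph`: `Wd` (directed weights),
#'   `mult` (multipliers), `W`, `t`.
#' @export
forward_bias_edges <- function(cg, t, cfg = walk_config()) {
  W <- cg$W
  ids <- rownames(W)
  if (is.null(names(t))) {
    if (length(t) != nrow(W)) stop("pseudotime does not cover all nodes")
    names(t) <- ids
  }
  if (!all(ids %in% names(t)) || any(!is.finite(t[ids])))
    stop("missing pseudotime entry for node(s): ",
         paste(setdiff(ids, names(t)[is.finite(t)]), collapse = ", "))
  tt <- t[ids]
  mult <- stats::plogis(cfg$b * outer(tt, tt, function(a, b) b - a))
  mult[W == 0] <- 0
  Wd <- W * mult
  dimnames(Wd) <- dimnames(mult) <- dimnames(W)
  structure(list(Wd = Wd, mult = mult, W = W, t = tt, b = cfg$b),
            class = "directed_cluster_graph")
}

# shared walk driver; returns first-visit steps, visit counts, end states
simulate_walks <- function(dg, root, cfg, terminals = integer(0),
                           stop_at_terminal = FALSE, stop_when_covered = FALSE,
                           seed_offset = 0L) {
  Wd <- dg$Wd
  n <- nrow(Wd)
  root_i <- match(as.character(root), rownames(Wd))
  if (is.na(root_i)) stop("root cluster not found: ", root)
  rs <- rowSums(Wd)
  P <- Wd / ifelse(rs > 0, rs, 1)
  cumP <- t(apply(P, 1L, cumsum))
  max_steps <- if (is.null(cfg$max_steps)) 1000L * n else as.integer(cfg$max_steps)
  term_i <- match(as.character(terminals), rownames(Wd)) - 1L
  set.seed(cfg$seed + seed_offset)
  res <- simulate_walks_cpp(cumP, rs, root_i - 1L, cfg$n_mcmc, max_steps,
                            cfg$x, cfg$alpha, as.integer(term_i),
                            stop_at_terminal, stop_when_covered)
  colnames(res$first_visit) <- colnames(res$visits) <- rownames(Wd)
  res$root_i <- root_i
  res
}

#' MCMC-refined pseudotime
#'
#' Simulates `n_mcmc` lazy-teleporting walks from the root on the
#' forward-biased directed graph and takes, per node, the first quartile
#' (type-7 linear-interpolation quantile) of the first-visit step counts over
#' the walks that visited it. Nodes never visited fall back to the biasing
#' pseudotime affinely mapped onto the refined scale, with a warning.
#'
#' @param dg A `directed_cluster_graph`.
#' @param root Root cluster id.
#' @param cfg A `walk_config`.
#' @return Named numeric vector `t_refined`; 0 at the root.
#' @export
mcmc_refine_pseudotime <- function(dg, root, cfg = walk_config()) {
  if (cfg$n_mcmc < 1L) stop("n_mcmc must be >= 1")
  n <- nrow(dg$Wd)
  if (n == 1L) return(stats::setNames(0, rownames(dg$Wd)))
  sim <- simulate_walks(dg, root, cfg, stop_when_covered = TRUE,
                        seed_offset = 1L)
  fv <- sim$first_visit
  t_ref <- vapply(seq_len(n), function(j) {
    v <- fv[, j]
    v <- v[v >= 0L]
    if (length(v) == 0L) NA_real_ else stats::quantile(v, 0.25, type = 7,
                                                       names = FALSE)
  }, numeric(1))
  names(t_ref) <- colnames(fv)
  if (anyNA(t_ref)) {
    miss <- names(t_ref)[is.na(t_ref)]
    warning("node(s) never visited by any walk, falling back to scaled ",
            "input pseudotime: ", paste(miss, collapse = ", "))
    tc <- dg$t
    ok <- !is.na(t_ref)
    rng_ref <- range(t_ref[ok])
    rng_tc <- range(tc[ok])
    scale <- if (diff(rng_tc) > 0) diff(rng_ref) / diff(rng_tc) else 1
    t_ref[!ok] <- rng_ref[1] + (tc[!ok] - rng_tc[1]) * scale
  }
  t_ref[sim$root_i] <- 0
  t_ref
}
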