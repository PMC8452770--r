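#' Specify a reference trajectory topology
#'
#' Builds the milestone network for one of the canonical topology kinds, or
#' validates a custom network against the declared kind. Branch lengths
#' default to 1 per edge.
#'
#' @param kind One of `"linear"`, `"bifurcation"`, `"multifurcation"`,
#'   `"cyclic"`, `"connected_hybrid"`, `"disconnected"`.
#' @param n_cells Number of cells (>= 10 per milestone).
#' @param n_features Number of features.
#' @param noise `"nb"` (negative binomial, default) or `"gaussian"`.
#' @param dispersion NB size parameter (default 5) or Gaussian sd.
#' @param marker_frac Fraction of features designated branch markers.
#' @param seed Integer seed.
#' @param milestones,edges Optional custom network: character milestone ids
#'   and a data frame `from`, `to`, `length`.
#' @return Object of class `topology_spec`.
#' @export
topology_spec <- function(kind = c("linear", "bifurcation", "multifurcation",
                                   "cyclic", "connected_hybrid",
                                   "disconnected"),
                          n_cells = 1000L, n_features = 1000L,
                          noise = c("nb", "gaussian"), dispersion = 5,
                          marker_frac = 0.2, seed = 42L,
                          milestones = NULL, edges = NULL) {
  kind <- match.arg(kind)
  noise <- match.arg(noise)
  if (is.null(edges)) {
    net <- canonical_network(kind)
    milestones <- net$milestones
    edges <- net$edges
  } else {
    if (is.null(milestones)) milestones <- unique(c(edges$from, edges$to))
    if (is.null(edges$length)) edges$length <- 1
  }
  ig <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                      vertices = milestones)
  has_cycle <- any(igraph::girth(igraph::as_undirected(ig))$girth >= 3) &&
    igraph::ecount(ig) >= igraph::vcount(ig) -
      igraph::components(ig)$no + 1L
  ncomp <- igraph::components(igraph::as_undirected(ig))$no
  if (kind %in% c("cyclic", "connected_hybrid") && !has_cycle)
    stop("kind '", kind, "' requires a cycle in the milestone network")
  if (kind %in% c("linear", "bifurcation", "multifurcation") && has_cycle)
    stop("kind '", kind, "' must be acyclic")
  if (kind == "disconnected" && ncomp < 2L)
    stop("kind 'disconnected' requires >= 2 components")
  if (kind != "disconnected" && ncomp > 1L)
    stop("kind '", kind, "' must be connected")
  if (n_cells < 10L * length(milestones))
    stop("need n_cells >= 10 * n_milestones (", 10L * length(milestones), ")")
  structure(list(kind = kind, milestones = milestones, edges = edges,
                 n_cells = as.integer(n_cells),
                 n_features = as.integer(n_features), noise = noise,
                 dispersion = dispersion, marker_frac = marker_frac,
                 seed = as.integer(seed)),
            class = "topology_spec")
}

canonical_network <- function(kind) {
  e <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(from = m[, 1], to = m[, 2], length = 1)
  }
  switch(kind,
    linear = list(milestones = paste0("M", 1:5),
                  edges = e("M1","M2", "M2","M3", "M3","M4", "M4","M5")),
    bifurcation = list(milestones = paste0("M", 1:4),
                       edges = e("M1","M2", "M2","M3", "M2","M4")),
    multifurcation = list(                   # two cascading bifurcations
      milestones = paste0("M", 1:8),
      edges = e("M1","M2", "M2","M3", "M2","M4",
                "M3","M5", "M3","M6", "M4","M7", "M4","M8")),
    cyclic = list(milestones = paste0("M", 1:5),
                  edges = e("M1","M2", "M2","M3", "M3","M4", "M4","M5",
                            "M5","M1")),
    connected_hybrid = list(                 # bifurcation hanging off a cycle
      milestones = paste0("M", 1:7),
      edges = e("M1","M2", "M2","M3", "M3","M4", "M4","M1",
                "M3","M5", "M5","M6", "M5","M7")),
    disconnected = list(                     # cycle + separate bifurcation
      milestones = paste0("M", 1:8),
      edges = e("M1","M2", "M2","M3", "M3","M4", "M4","M1",
                "M5","M6", "M6","M7", "M6","M8")))
}

#' Simulate a single-cell matrix along a reference topology
#'
#' Cells are placed uniformly along milestone edges (proportionally to branch
#' length). Each feature's mean is piecewise-linear between per-milestone
#' archetype levels drawn from a log-normal prior; a `marker_frac` share of
#' features are branch markers whose level ramps up monotonically along one
#' designated edge. Counts are drawn from the configured noise model. True
#' time is the path distance from the component root, normalized to `[0, 1]`
#' per component (cycles are parameterized by progress around the loop from
#' the start milestone).
#'
#' @param spec A `topology_spec`.
#' @return List with `X` (counts matrix, cells x features) and `ref`, an
#'   object of class `reference_trajectory`: `milestones`, `edges`, `cells`
#'   (data frame: cell_id, edge, position, true_time, branch, type,
#'   component, is_terminal_branch), `terminal_milestones`, `roots` (one
#'   milestone per component).
#' @export
simulate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "topology_spec"))
  set.seed(spec$seed)
  ms <- spec$milestones
  ed <- spec$edges
  nm <- length(ms)
  nf <- spec$n_features
  nc <- spec$n_cells
  ig <- igraph::graph_from_data_frame(ed[, c("from", "to")], vertices = ms)
  comp <- igraph::components(igraph::as_undirected(ig))$membership
  # component roots: first milestone (by declared order) with in-degree 0,
  # else the first milestone of the component (cycle start)
  indeg <- igraph::degree(ig, mode = "in")
  roots <- vapply(seq_len(max(comp)), function(ci) {
    cand <- ms[comp == ci & indeg[ms] == 0]
    if (length(cand) > 0) cand[1] else ms[comp == ci][1]
  }, character(1))
  outdeg <- igraph::degree(ig, mode = "out")
  terminal_ms <- ms[outdeg == 0]
  # milestone times: path distance from the component root (hops weighted by
  # branch length); on cycles, distance along the forward direction
  tm <- rep(NA_real_, nm); names(tm) <- ms
  for (ci in seq_len(max(comp))) {
    sub <- ms[comp == ci]
    d <- igraph::distances(ig, v = roots[ci], to = sub, mode = "out",
                           weights = ed$length)[1, ]
    tm[sub] <- d
  }
  # cell placement
  probs <- ed$length / sum(ed$length)
  eidx <- sample.int(nrow(ed), nc, replace = TRUE, prob = probs)
  u <- stats::runif(nc)
  from <- ed$from[eidx]; to <- ed$to[eidx]
  raw_t <- tm[from] + u * ed$length[eidx]
  cell_comp <- comp[from]
  true_time <- raw_t
  for (ci in seq_len(max(comp))) {
    sel <- cell_comp == ci
    span <- max(true_time[sel])
    true_time[sel] <- if (span > 0) true_time[sel] / span else 0
  }
  branch <- paste0(from, "->", to)
  type <- ifelse(u < 0.5, from, to)
  # archetype log-normal levels; markers ramp along one designated edge
  A <- matrix(stats::rlnorm(nm * nf, meanlog = log(2), sdlog = 0.8), nm, nf,
              dimnames = list(ms, NULL))
  n_mark <- floor(spec$marker_frac * nf)
  marker_edge <- rep(NA_integer_, nf)
  if (n_mark > 0) {
    mk <- seq_len(n_mark)
    marker_edge[mk] <- rep_len(seq_len(nrow(ed)), n_mark)
    amp <- stats::rlnorm(n_mark, meanlog = log(8), sdlog = 0.3)
    A[cbind(match(ed$to[marker_edge[mk]], ms), mk)] <-
      A[cbind(match(ed$from[marker_edge[mk]], ms), mk)] + amp
  }
  mu <- (1 - u) * A[from, , drop = FALSE] + u * A[to, , drop = FALSE]
  X <- if (spec$noise == "nb") {
    matrix(stats::rnbinom(nc * nf, mu = as.vector(mu), size = spec$dispersion),
           nc, nf)
  } else {
    mu + matrix(stats::rnorm(nc * nf, sd = spec$dispersion), nc, nf)
  }
  dimnames(X) <- list(sprintf("cell_%04d", seq_len(nc) - 1L),
                      sprintf("feat_%04d", seq_len(nf) - 1L))
  cells <- data.frame(cell_id = rownames(X), edge = eidx, position = u,
                      true_time = unname(true_time), branch = branch,
                      type = type, component = unname(cell_comp),
                      is_terminal_branch = to %in% terminal_ms,
                      row.names = NULL)
  ref <- structure(list(milestones = ms, edges = ed, cells = cells,
                        terminal_milestones = terminal_ms, roots = roots,
                        kind = spec$kind, marker_edge = marker_edge,
                        archetypes = A),
                   class = "reference_trajectory")
  list(X = X, ref = ref)
}

#' Write the reference files of a simulated trajectory
#'
#' Writes the milestone edge list (TSV) and per-cell truth table (CSV)
#' alongside the matrix.
#' @param sim Result of [simulate_trajectory()].
#' @param dir Output directory (created if needed).
#' @param format Matrix format for [write_matrix()].
#' @export
write_reference <- function(sim, dir, format = "csv") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(sim$X, file.path(dir, paste0("matrix.", format)), format)
  write_edge_list(data.frame(source = sim$ref$edges$from,
                             target = sim$ref$edges$to,
                             weight = sim$ref$edges$length),
                  file.path(dir, "milestone_network.tsv"))
  utils::write.csv(sim$ref$cells[, c("cell_id", "true_time", "branch",
                                     "type", "is_terminal_branch")],
                   file.path(dir, "cell_truth.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}
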