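# trajwalk

Trajectory inference for single-cell omics by lazy-teleporting random walks
on cluster graphs.

Single-cell snapshots (scRNA-seq, scATAC-seq, CyTOF, image-derived
morphological profiles) sample a continuum of cell states. `trajwalk`
reconstructs that continuum — a root-anchored **pseudotime**, the branching
structure, the **terminal cell fates**, and per-cell **lineage
probabilities** — without forcing the data onto a tree or an absorbing
Markov chain, so multifurcating, cyclic, hybrid and disconnected topologies
all survive inference.

## Method in brief

Cells are joined in an exact KNN affinity graph, clustered (Leiden by
default, k-means as a substitute), and aggregated into a weighted cluster
graph `G(V, E, W)`. On `G`, with `P = D^-1 W`, the method runs a
*lazy-teleporting* random walk

    Z  = x P + (1 - x) I            (stay put with probability 1 - x)
    Z' = a Z + (1 - a) J / n        (teleport uniformly with probability 1 - a)

Pseudotime of cluster `r` is the expected hitting time of `r` from the root
under `Z'`, computed in closed form from the full eigendecomposition
`(Phi_m, eta_m)` of the symmetric normalized Laplacian:

    R = sum_m Phi_m Phi_m' / (beta + 2 x (1 - beta) eta_m),
    beta = 2 (1 - a) / (2 - a),     M = D^-1/2 R D^-1/2,
    h(root -> r) = n (M[r,r] - M[root,r]) / ((1 - a) sum_q M[q,r])

which matches a dense first-hitting linear solve on `Z'` to below `1e-8`
relative error (tested on dozens of random graphs). Edges are then
forward-biased with the logistic multiplier
`f(i -> j) = 1 / (1 + exp(-b (t_j - t_i)))`, `b = 1`, and pseudotime is
refined as the first quartile of first-visit times over thousands of
simulated walks — an estimator that is robust to spurious weak edges.
Terminal states are detected by a consensus vote over directed-graph
connectivity (out-degree, closeness, betweenness) gated on being a local
pseudotime maximum; lineage likelihoods are walk visitation frequencies
(visits during walks that reach a terminal / visits during all walks), and
everything is projected back to single cells through the KNN graph for
imputation and lineage-weighted expression trend curves.

A seeded simulator of reference topologies (linear, bifurcation, cascading
multifurcation, cyclic, connected hybrid, disconnected) and a
trajectory-scoring suite (Ipsen–Mikhailov spectral distance, graph edit
distance, branch/fate F1, temporal Pearson correlation, composite accuracy)
are included, so every stage is testable against known truth.

## Worked example

```r
library(trajwalk)

# 1000 cells x 1000 genes along two cascading bifurcations (4 leaf fates)
sim <- simulate_trajectory(topology_spec("multifurcation", seed = 3))
fit <- trajwalk(sim$X, root = "M1", root_mode = "group_label",
                annotations = sim$ref$cells$type,
                k = 20, n_pcs = 10, log1p = TRUE, seed = 1)
fit
#> Lazy-teleporting random-walk trajectory fit
#>   1000 cells, 14 clusters, 1 component(s)
#>   root cluster: 10   terminal states: 5, 6, 12, 13

score_trajectory(fit, sim$ref)
#> Trajectory score report
#>   IM distance      0.0000
#>   edit distance    0 (max 30)
#>   F1 branch        1.0000
#>   temporal Pearson 0.8973
#>   F1 cell fate     1.0000
#>   composite        97.95 / 100
```

The fit found 14 clusters forming one connected component; the four
detected terminal clusters map onto exactly the four reference leaf fates
(cell-fate F1 = 1), every reference branch is recovered with no spurious
ones (branch F1 = 1, edit distance 0), and cell-level pseudotime correlates
0.90 with true simulation time. `predict(fit, "pseudotime")` and
`predict(fit, "lineage")` return the per-cell values; `plot(fit)` draws the
cluster graph coloured by pseudotime; `summary(fit)` prints the per-cluster
table and the terminal-state vote.

`run_pipeline()` writes the full output bundle (assignments, graphs,
pseudotime, terminal states, lineage matrices, trend curves, manifest) and
is wrapped by a small CLI with `simulate` / `infer` / `score` / `trends`
subcommands at `inst/cli/trajwalk-cli.R`.

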