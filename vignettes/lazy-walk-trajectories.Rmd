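---
title: "Trajectory inference with lazy-teleporting random walks: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory inference with lazy-teleporting random walks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajwalk)
```

## The problem

Single-cell snapshots (transcriptomes, chromatin accessibility, protein or
morphological profiles) sample a continuum of cell states. Trajectory
inference reconstructs the latent ordering of that continuum — a *pseudotime*
anchored at a user-chosen root state — together with its branching structure
and terminal cell fates. Tree-shaped differentiation is the easy case; cyclic
processes (cell cycle), hybrid topologies and disconnected populations break
methods that force the data onto a tree or an absorbing chain. `trajwalk`
works on a weighted cluster graph and deliberately avoids pruning edges or
absorbing states, so cyclic and disconnected structure survives inference.

## Model

### Cluster graph

Cells are connected in an exact K-nearest-neighbour graph with a locally
adaptive Gaussian kernel: the directed affinity from cell $i$ to neighbour
$j$ is $\exp(-d_{ij}^2/\sigma_i^2)$ with $\sigma_i$ the mean distance from
$i$ to its $K$ neighbours, symmetrised by elementwise maximum (union). The
union keeps edges into rare populations that only one side nominates. Cells
are grouped by Leiden community detection (k-means is available as a
substitute); cluster-to-cluster edge weights are the *sum* of inter-cluster
single-cell affinities, so the edge strength reflects how many cells carry
the connection. A `mean` aggregation is available where population sizes
should not matter.

By default the fitter prunes a cluster-graph edge when its weight is below
0.3 times the strongest incident edge of *both* endpoints, and never removes
a maximum-spanning-forest edge, so pruning cannot disconnect a component.
The threshold is local on purpose: a spurious long-range link between two
well-connected hubs is weak relative to both endpoints and is dropped, while
the genuinely weak closing edge of a sparse ring is each endpoint's best
link and survives — a global median threshold would cut it and destroy the
cycle. Setting `prune_frac = 0` disables pruning (and is the default of
the exported `build_cluster_graph()`, which keeps the exact conservation
property: the total cluster-edge weight equals the total inter-cluster
single-cell weight).

### Lazy-teleporting walk and closed-form pseudotime

With $W$ the symmetric weight matrix, $D$ the diagonal degree matrix and
$P = D^{-1}W$, the walk operators are

$$Z = xP + (1-x)I, \qquad Z' = \alpha Z + (1-\alpha)\tfrac{1}{n}J,$$

i.e. each step teleports uniformly with probability $1-\alpha$, otherwise
stays put with probability $1-x$, otherwise moves along an edge. On a plain
walk the expected hitting time is dominated by the stationary distribution —
local degree information — as data grow; the small teleport and laziness
probabilities re-weight the spectrum so that global eigenpairs keep
contributing.

Pseudotime of cluster $r$ is the expected number of steps for the walk
started at the root to first reach $r$. Writing
$L = I - D^{-1/2}WD^{-1/2}$ for the symmetric normalized Laplacian with
eigenpairs $(\Phi_m, \eta_m)$, $\beta = 2(1-\alpha)/(2-\alpha)$ and

$$R = \sum_m \frac{\Phi_m\Phi_m^{\mathsf T}}
                  {\beta + 2x(1-\beta)\eta_m},
  \qquad M = D^{-1/2} R\, D^{-1/2},$$

the personalized-PageRank identity
$\beta M D = (1-\alpha)(I-\alpha Z)^{-1} = G$ (the PageRank matrix with
restart $1-\alpha$) links the spectral quantity to the chain: absorbing the
target $r$ in $Z'$ and solving $(I - Z'_{-r})h = \mathbf 1$ gives, after
eliminating the self-consistent teleport term,

$$h(q \to r) \;=\; \frac{G_{rr} - G_{qr}}{(1-\alpha)\,\overline{G_{\cdot r}}}
             \;=\; \frac{n\,(M_{rr} - M_{qr})}{(1-\alpha)\sum_q M_{qr}}.$$

The numerator is the usual spectral difference; the denominator is the exact
per-target scale that converts it into walk steps. The package computes this
closed form from one eigendecomposition of $L$ (dimension = number of
clusters, so all eigenpairs are kept; no truncation threshold exists to
tune). The test suite verifies it against a dense first-hitting linear solve
on $Z'$ to below $10^{-8}$ relative error on dozens of random graphs, and
checks that as $\alpha, x \to 1$ it converges to classical random-walk
hitting times. At $\alpha = 1$ exactly the resolvent is singular
($\beta = 0$); `spectral_cache()` raises a degenerate-parameter error rather
than returning garbage.

Teleport arrivals count as hits; this is the variant that matches the
absorbed-chain derivation above, and it is also how the Monte-Carlo
simulator counts visits, so the two stages are consistent.

### Forward biasing and Monte-Carlo refinement

Edges are never pruned by direction. Each undirected edge $\{i,j\}$ is
split into two directed edges with logistic multipliers
$f(i\to j) = 1/(1 + e^{-b\,(t_j - t_i)})$, $b = 1$, which sum to 1 and give
the orientation toward later pseudotime the larger share. Because hitting
times are in step units of arbitrary magnitude, the fitter rescales
pseudotime to $[0, 10]$ per component before biasing: with raw hitting
times (often spanning hundreds of steps) the logistic saturates, the graph
becomes effectively irreversible, and walkers that commit to one branch can
never return to visit the others — which distorts the refinement and any
cross-branch time comparison. The $[0,10]$ span keeps typical
adjacent-cluster differences (about $10/\text{path length}$) inside the
logistic's sensitive region while still orienting the flow clearly. The
biasing operator itself (`forward_bias_edges()`) is scale-faithful — it
applies exactly the multiplier above to whatever pseudotime it is given.

Because directed graphs admit no closed-form hitting times, pseudotime is
refined by simulating `n_mcmc` lazy-teleporting walks from the root on the
biased graph (C++ inner loop, R's RNG, reproducible under a seed) and
taking, per node, the *first quartile* of first-visit step counts over the
walks that visited it (type-7 linear-interpolation quantile, pinned for
bit-reproducibility). The lower quartile is what makes the estimate robust:
a spurious weak long-range edge changes a small minority of walks, which
moves the upper tail of first-visit times but barely the lower quartile.
The acceptance suite measures exactly this: adding a long-range edge at 1%
of the median weight leaves the refined rank order essentially intact
(Spearman above 0.95). Nodes that no walk reached fall back to the biasing
pseudotime affinely mapped onto the refined scale, with a warning.

### Terminal states

The directed graph is re-biased with the refined pseudotime and each node is
scored on three connectivity metrics of the unweighted forward view (an edge
$i \to j$ is kept when its multiplier is at least 0.5): closeness
$C(q) = 1/\sum_r l(q,r)$ over the nodes $q$ reaches, betweenness
$B(q) = \sum \sigma_{rt}(q)/\sigma_{rt}$, and the weighted out-degree. Two
conventions matter and are worth stating. Dead ends reach nothing, so their
distance sum is empty and $C$ is taken as $+\infty$ — the leaf-like extreme
(a fully isolated node gets 0 and is flagged). Betweenness sums ordered
pairs and is halved, counting each endpoint pair once; only medians of the
metric are used, so the scale is immaterial.

A node is terminal iff

1. it is a **local pseudotime maximum** of the directed graph (no
   strictly-forward neighbour — no outgoing differentiation flow) with
   refined pseudotime at or above the component median, and
2. it wins the consensus vote: out-degree at or below median, closeness
   strictly above median, betweenness at or below median.

The local-maximum condition is the package's resolution of an ambiguity in
median votes: on branches split across several clusters, the penultimate
cluster (which relays flow into the leaf) also sits in the leaf-like half of
every median split, while only the final cluster has no forward neighbour.
The "at or above median" pseudotime comparison is deliberately non-strict —
with an even number of clusters a genuine leaf on a fast branch can sit
exactly at the interpolated median. The strict closeness vote is what keeps
degenerate inputs honest: on a complete graph with uniform pseudotime no
node exceeds the median closeness, so the terminal set is empty and a
warning is issued. Vote directions and quorum are configurable, and the
per-node ledger of every vote is returned for audit.

### Lineage likelihoods and single-cell projection

Lineage probabilities are visitation frequencies, not absorbing-chain
solutions: walks start at the root on the biased graph and end on first
arrival at any terminal; the likelihood that cluster $i$ belongs to the
lineage of terminal $j$ is (visits to $i$ during $j$-successful walks) /
(visits to $i$ during all walks). Ending at the first terminal reached is
the package's reading of "successful path": with teleportation active a
non-terminating walk would eventually visit every node and all ratios would
degenerate to 1. A teleport step can land on a terminal and end a walk;
with the default $1-\alpha = 0.01$ this affects a percent-scale fraction of
walks and is part of the model's stochasticity. On tree-shaped toys these
frequencies converge to the analytic absorption probabilities (tested
within three standard errors).

Cluster-level pseudotime and lineage probabilities are projected to cells
through the single-cell KNN graph: one smoothing pass sets each cell to the
affinity-weighted mean of its neighbours' cluster values (`n_smooth = 1`
by default); the projection is a convex combination, so cell values never
leave the range of cluster values.

### Imputation and trend curves

Feature imputation diffuses the matrix with the row-normalized affinity
operator, $X^{(t)} = T^t X$, default $t = 3$ steps: enough to share
information across a neighbourhood, few enough not to blur branch
boundaries (as $t$ grows values converge to the per-component
degree-weighted mean, which the tests verify). Expression trends per
lineage are weighted penalized B-spline fits (`mgcv::gam`, cubic basis,
basis dimension 10, GCV-selected penalty) of a feature against cell-level
pseudotime with lineage probabilities as prior weights, evaluated on a
100-point uniform grid over the pseudotime range of positively weighted
cells; extrapolation is not performed. Zero-weight cells are excluded
exactly, so a lineage's curve is unaffected by cells that cannot reach it.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `k` | 30 (20 on the simulated benchmarks) | KNN neighbour count; unitless |
| `resolution` | 1.0 | Leiden resolution; larger gives more clusters |
| `prune_frac` | 0.3 (fitter) / 0 (exported op) | weak-edge threshold as fraction of median weight; spanning forest always kept |
| `x` | 0.95 | move probability (laziness $1-x = 0.05$); small laziness suffices to damp the stationary term |
| `alpha` | 0.99 | non-teleport probability; $1-\alpha = 0.01$ injects global connectivity without flattening local structure |
| `b` | 1 | logistic growth factor of the forward bias |
| `n_mcmc` | 1000 | simulated walks per stage |
| `max_steps` | $1000 \cdot n_\text{clusters}$ | per-walk cap |
| `n_smooth` | 1 | projection smoothing passes |
| `t_steps` | 3 | imputation diffusion steps |
| `seed` | 42 | threaded through clustering and every simulation |

## The synthetic generator

`simulate_trajectory()` emulates the statistical structure of reference
trajectory simulators: milestones on a known network (linear, bifurcation,
two cascading bifurcations with four leaves, five-milestone cycle, a
bifurcation hanging off a cycle, and a disconnected cycle + bifurcation
pair); cells placed uniformly along edges; per-milestone archetype
expression levels from a log-normal prior (meanlog $\log 2$, sdlog 0.8)
interpolated piecewise-linearly along edges; 20% of features are branch
markers that ramp up monotonically along one designated edge
(amplitude around $8\times$); counts drawn from a negative binomial
(dispersion size 5) on those means, with a Gaussian alternative. True time
is path distance from the component root normalized to $[0,1]$ per
component; cycles are parameterized by progress around the loop; terminal
fates are the out-degree-zero milestones.

The defaults — 1000 cells, 1000 features, ten principal components after
`log1p`, $K = 20$ — are the conditions of the package's benchmark suite and
mirror common simulated TI benchmarks. What the generator does **not**
emulate: library-size variation, zero inflation beyond the NB, batch
effects, doublets, or correlated gene modules. Passing the recovery tests
therefore shows the inference machinery is correct on clean
known-truth data, not that it is robust to every artefact of real
sequencing data; on real data the clustering granularity and `prune_frac`
deserve attention.

## Evaluation metrics

Inferred clusters are mapped to reference milestones by majority cell type
(ties to the lexicographically first label), and the cluster graph is
contracted to a milestone-level graph. Against the reference network the
package computes: the spectral distance between Lorentzian-smoothed
Laplacian frequency densities, with the half-width $\gamma$ calibrated per
node count so that empty-vs-complete equals exactly 1 (unequal sizes are
padded with isolated nodes); unit-cost graph edit distance — exact
symmetric difference in the shared label space, or an exact
branch-and-bound search up to 12 nodes for unlabeled graphs; branch-level
and fate-level F1 scores $tp/(tp + \tfrac12(fp+fn))$; Pearson correlation
of cell-level pseudotime with true time (constant vectors are an error,
never a silent zero). The composite score converts each metric to a
percentage — $100(1-\text{IM})$, $100(1-\text{GED}/\text{GED}_{\max})$
with $\text{GED}_{\max}$ the cost of editing both graphs to empty, F1s and
the zero-clamped correlation times 100 — and averages them (four metrics
when lineage prediction is excluded). The conversion formulas for the two
graph distances are the package's own choice; only the percentage-mean
construction is inherited.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_trajectory(topology_spec("multifurcation", seed = 3))
fit <- trajwalk(sim$X, root = "M1", root_mode = "group_label",
                annotations = sim$ref$cells$type,
                k = 20, n_pcs = 10, log1p = TRUE, seed = 1)
summary(fit)
score_trajectory(fit, sim$ref)
plot(fit)
```

## Numerical and degenerate-input choices

- Quantiles are type-7; KNN ties break by cell index; root tie-breaks by
  degree rank, betweenness rank, then lowest cluster id — everything that
  could differ between runs is pinned, and two runs with the same seed
  write byte-identical outputs.
- Components are processed independently. A component that does not contain
  the requested root is anchored at its node of maximal eccentricity (tie:
  lowest id) and flagged in `roots`; its pseudotime is relative to that
  anchor and not comparable across components.
- Single-node components get pseudotime 0 and no terminals.
- `alpha = 1` is valid for the operators and the simulator but not for the
  closed form (singular resolvent, explicit error). Isolated nodes in a
  multi-node component are a graph error for the walk operators.
- Walks at a dead end (possible only in hand-built directed graphs) end
  when `x = alpha = 1`, otherwise wait in place.

## Limitations

- Pseudotime is a hitting time: its absolute scale is walk steps, not
  biological time; only the ordering and relative magnitudes are
  meaningful, and branch-to-branch comparability depends on reasonably
  balanced edge weights (the refinement mitigates, but cannot remove, rate
  differences between branches).
- Terminal detection assumes terminal states are late *and* leaf-like in
  the directed graph; a cycle with a pseudotime gradient will yield one
  "latest" node that can pass the vote — harmless for scoring (cyclic
  references define no fates) but worth knowing when interpreting output.
- Exact KNN is quadratic in cells; for inputs far beyond $10^4$ cells an
  approximate neighbour backend behind `build_knn_graph()`'s interface
  would be the natural extension.
- The h5ad container is not read directly; export such data to CSV/MTX
  first.
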