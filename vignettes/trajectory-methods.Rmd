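---
title: "Trajectory and pseudotime inference for cytometry data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory and pseudotime inference for cytometry data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytotrail)
```

# The problem

Flow and mass cytometry measure tens of protein markers on up to millions of
single cells. In differentiation and reprogramming experiments the cells of a
sample do not form discrete types so much as a continuum: progenitors drift
through intermediate states toward several terminal fates. cytotrail
reconstructs that continuum as a *tree-shaped trajectory* over cell clusters
and assigns every cell a *pseudotime* — a scalar in [0, 1] ordering cells
along the process — plus a score identifying *intermediate-state* cells that
sit on the main routes between the origin and the termini.

The workflow is strictly staged, and each stage records itself in an
append-only log carried by the `cyto_state` container:

preprocess → cluster → (downsample) → (embed) → tree → branches →
KNN graph → roots → pseudotime → leaves → walk.

Re-running a stage clears everything downstream of it, so a state object can
never mix results from incompatible upstream runs.

# Preprocessing

`read_fcs()` parses single-dataset FCS 3.0/3.1 files (float, double and
integer storage; little- and big-endian; log-amplified `$PnE` parameters are
linearized as `10^(f1 x / $PnR) * f2` on read). Compensation solves
`X' S = X` for the spillover matrix `S` (rows = detectors, columns =
fluorochromes, unit diagonal), touching only the channels `S` names. Gates
are axis-aligned closed intervals; a cell must satisfy every gate
(intersection). The default normalization is `asinh(x / 5)` — the mass
cytometry convention; fluorescence data typically use a larger cofactor
(~150), which is exposed. The fixed preprocessing order is **compensate →
gate → transform**: compensation must see raw linear intensities, and gating
on compensated (but untransformed) channels matches how gates are drawn on
conventional cytometry plots. The order is written to the log with the
transform parameters.

Time-course experiments are merged with `merge_samples()`, which draws a
fixed number of cells (default 2,000) per sample uniformly without
replacement before concatenating, so no time point dominates. The draw for
each cell is keyed on `(seed, sample label, cell id)`, which makes the
selection independent of both sample order and row order — two runs with the
same seed select the same cells no matter how the inputs were arranged.

Batch correction is deliberately delegated: `set_corrected_values()` accepts
a matrix corrected by an external tool (e.g. ComBat) and installs it after a
shape/dimname check. The package does not model batch effects itself.

# Clustering

The default clusterer is a self-organizing map on a 6×6 rectangular grid —
36 prototype vectors ("codes") trained competitively; each cell's cluster is
its nearest code by Euclidean distance. Training is online with a bubble
neighbourhood: the radius shrinks linearly from two thirds of the grid
diameter to zero and the learning rate from 0.05 to 0.01 over `rlen = 8`
passes. Codes are initialized from a spread (kmeans++-sampled) subset of the
data rows.

Classic online SOM can leave *dead units* — grid nodes that win no cells —
when the data contain populations at very different separations. Because the
number of occupied nodes is the de facto cluster count, `som_fit()` finishes
with a batch polish: map all cells, recenter each node on its members,
re-seed any empty node at the cell worst represented by its current winner,
and iterate (at most 20 rounds) until the mapping is stable. On data with at
least 36 well-separated populations the default grid then reliably yields
exactly 36 clusters; `polish = FALSE` disables the phase for a pure online
map.

`kmeans` (kmeans++ seeding, empty clusters re-seeded from the farthest
point) and `hclust` (Ward.D2 linkage, Euclidean distance) are provided via
the corresponding base R routines; `clara`- or PhenoGraph-style methods hook
in through `method = "plugin"` with a user callable. All stochastic methods
see rows sorted by cell id, so labelings are invariant (up to renaming) to
row permutation under a fixed seed.

**Cluster-dependent downsampling** subsamples each cluster separately,
keeping `max(1, ceiling(fraction * size))` cells, so rare populations are
never lost — uniform downsampling of a 100,000-cell sample at 1% would
routinely delete a 50-cell progenitor cluster that this scheme preserves.

# Dimensionality reduction

PCA (exact, centred SVD), tSNE and UMAP (seeded, via Rtsne and uwot) and a
diffusion map are available at cell level (kept cells) or cluster level
(centroids). The diffusion map follows the standard construction: Gaussian
kernel `K = exp(-d²/2σ²)`, density normalization `K/(q qᵀ)` with
`q = rowSums(K)` (removing sampling-density bias), row-normalization to a
Markov matrix, and the top non-trivial right eigenvectors scaled by their
eigenvalues as coordinates. The bandwidth default `σ = "auto"` is the median
non-zero pairwise distance — a scale at which a typical point sees a
meaningful neighbourhood; it is stored in the result. Eigenvector signs are
fixed (largest-magnitude entry positive) for reproducibility. Nonlinear
cell-level embeddings refuse to run above 100,000 kept cells unless forced;
downsampling first is both faster and statistically harmless at that scale.

The cluster centroid in any space is the arithmetic mean of its member cells
— all clustered cells in expression space, kept cells only in embedding
space (embeddings exist only for kept cells; recomputing centroids from a
different cell set would mix spaces).

# The trajectory tree

The trajectory is the minimum spanning tree of the complete Euclidean graph
over cluster centroids, in expression space by default (markers are few, so
distances are meaningful without reduction) or any computed embedding.
Kruskal's algorithm runs on edges sorted by `(weight, smaller id, larger
id)`, making the tree deterministic even under exact distance ties.

Branches are Louvain communities of the tree with edge affinity `1/weight`:
modularity treats larger weights as stronger ties, so affinities — not
distances — are what the algorithm must see, and a long edge (a jump across
marker space) becomes a natural branch boundary. The resolution parameter
(default 1.0) is exposed; larger values cut the tree into more branches. On
trees the Louvain backend is deterministic; the seed is fixed and logged
regardless.

Per-branch differential markers use a pooled-variance two-sample t test of
each branch against all other cells, with Benjamini–Hochberg adjustment
across all (branch, marker) pairs. With tens of markers and hundreds-to-
thousands of cells per branch, empirical-Bayes variance moderation would
change essentially nothing, so the plain t statistic is used; the test suite
verifies both agreement with `t.test()` and type-I calibration on 1,000 null
markers. Branches with fewer than 2 cells are skipped with a warning record.

# Pseudotime

Pseudotime is estimated in four steps on the cells themselves (not the
clusters):

1. the user defines **root cells** (by id or as whole clusters), whose
   pseudotime is zero by definition;
2. a KNN graph connects every kept cell to its `k` nearest neighbours
   (Euclidean; edge set symmetrized by union; weight = distance); the
   default `k = min(30, ceiling(sqrt(n)))` grows slowly with the cell count
   and is capped to keep the graph sparse;
3. weighted shortest-path distances `dist(i, j)` from every cell to every
   root are computed;
4. each cell's distance field and pseudotime are

   `D_i = mean_j dist(i, j)` over the `n` root cells, and
   `pt_i = (D_i − min D) / (max D − min D)`,

   after which root cells are forced to exactly 0.

Degenerate cases are handled explicitly and logged: if `max D = min D`
(e.g. every cell is a root) all pseudotime is 0; a cell unreachable from
every root gets the maximum finite `D` — mapping it to pseudotime 1 rather
than inventing connectivity — and a cell reachable from only some roots
averages over the reachable ones. If no root reaches any non-root cell the
run fails with advice to increase `k`.

**Leaf cells** — the termini of the process — are chosen explicitly or
automatically as the cells at or above the `1 − q` pseudotime quantile
(default top 2%). Leaves must be disjoint from roots; automatic selection
skips root cells.

# Orientation and walks

The KNN graph is oriented by the descent rule: every edge points from its
higher-pseudotime endpoint to the lower one. Taken literally this means
paths can only *descend* pseudotime — which would make a root-to-leaf walk
impossible — so the backward walk (leaf → root) runs on the orientation
itself and the forward walk (root → leaf) on its reverse. Equal-pseudotime
edges stay bidirected: dropping them could disconnect the walks, and their
count is logged.

For every (root, leaf) pair, one forward and one backward weighted shortest
path are computed with Dijkstra's algorithm under a deterministic tie-break
(on equal distance, the predecessor with the lexicographically smaller cell
id wins, and equal-distance nodes settle in id order), so walk counts are
exactly reproducible and testable against exhaustive path enumeration. A
cell's **walk count** is the number of such paths through it; cells
(excluding roots and leaves) whose count reaches the 80th percentile of the
positive interior counts are flagged **intermediate-state** — the cells the
process funnels through. Pairs with no connecting path are recorded and
skipped, not fatal. Weighted (not hop-count) paths are used for consistency
with the distance definition in step 3.

# The synthetic generator

`simulate_tree_data()` generates branching data with known truth: cells are
placed uniformly along the unit-length segments of a rooted tree, each
segment carries a linear marker program (child programs start at the
parent's end, so trajectories are continuous), and observed values add
independent Gaussian noise. True pseudotime is the root-to-cell distance
along the tree normalized by the deepest leaf. Default study conditions,
used throughout the tests: a 3-armed star (200 root + 3×200 arm cells), 10
markers, noise SD 0.1 against unit-length segments, seed 7.

Sibling segments take maximally dispersed (simplex) unit directions,
pairwise cosine −1/(m−1), in a random subspace orthogonal to the parent's
direction; a single child continues its parent's direction. Diverging
directions are the point of a branching process — with uniformly random
directions two arms can fold onto each other and even the noiseless
cluster-level MST could not reproduce the generating topology. Linear (not
sigmoidal) programs are the simplest structure that exercises monotone ramp
detection; Gaussian, marker-independent noise is a deliberate
simplification.

What the generator does *not* emulate: spillover, debris and doublets,
heavy-tailed or correlated noise, density variation along the trajectory,
and cell-cycle-like confounders. Passing the recovery tests therefore shows
the algorithms are implemented correctly, not that real cytometry data will
be as benign. `simulate_samples_over_time()` adds a drifting time-course
layout for exercising sample merging, and `simulate_blobs()` provides
well-separated Gaussian populations for clustering checks.

# Numerical choices and problem sizes

* Compensation inverts the spillover matrix with `solve()`; singularity is a
  user-facing error, not an approximation.
* MST, Dijkstra and the pseudotime formula are verified against brute-force
  oracles (spanning-tree enumeration over all Cayley trees up to 6 nodes,
  Floyd–Warshall up to 60 nodes, exhaustive shortest-path enumeration on
  15-node graphs) at tolerance 1e-9.
* Dijkstra equality uses an absolute tolerance of 1e-12 when comparing path
  sums, so floating-point noise cannot flip a tie-break.
* The test suite runs on hundreds-to-thousands of cells (star fixture: 800;
  SOM check: 3,600) — sizes at which every oracle is exact and the whole
  suite completes in well under a minute; the algorithms themselves scale to
  the 10⁵-cell guard above.

# Known limitations

* Orientation of the trajectory comes entirely from the user's root choice;
  there is no data-driven directionality (no velocity-style inference).
* Pseudotime is global, not branch-aligned: two cells at the same depth on
  different arms share a pseudotime value.
* The Louvain resolution default (1.0) can merge short branches on very
  compact trees; raise it when the tree is small and tight.
* The FCS dialect is deliberately minimal: single-dataset files, no analysis
  segment, no write-side integer/log storage.
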