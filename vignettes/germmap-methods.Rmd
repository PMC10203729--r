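---
title: "germmap: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{germmap: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`germmap` reconstructs three views of an in vitro differentiation time
course: what each cell is (label transfer from an annotated reference),
where it belongs in a spatially resolved embryo (SNN-weighted projection),
and where it came from (optimal-transport lineage tracing). This vignette
is the package's own account of the underlying models, the parameters that
matter, and the choices made where the methods literature leaves the
design open. It states no empirical claim that the test suite and
`scripts/acceptance.R` do not themselves compute.

## Label transfer by hypergeometric KNN enrichment

For a query cell with `k` nearest reference neighbours (Euclidean, in a
shared embedding), each candidate annotation is tested for *enrichment*
among the neighbours: with `K` cells of that annotation in a reference of
size `N` and `x` among the neighbours, the score is the one-sided upper
tail `P(X >= x)` of `Hypergeom(N, K, k)`. Enrichment (not depletion) is
the scientific question, hence one-sided. Key choices:

* **Adjustment family.** p-values are Benjamini–Hochberg adjusted *within
  each cell*, across its candidate annotations. The alternative — one
  global family across all cells — would couple unrelated cells'
  assignments and make single-cell results depend on batch composition.
  With per-cell families, the per-cell false-assignment rate is controlled
  directly; the shuffled-label control in the test suite confirms the
  empirical assignment rate stays at the alpha scale.
* **Defaults.** `k = 20` neighbours and `alpha = 0.05`. `k` trades
  sensitivity (larger neighbourhoods can detect subtler enrichment)
  against locality; 20 is the common neighbourhood scale in single-cell
  graphs at the 10^3–10^4-cell reference sizes this package targets.
* **Degenerate case.** If one annotation covers the whole reference,
  `x = k = K = N` gives `p = 1` (drawing that label is certain, so there
  is no evidence of enrichment) and the cell stays `UNASSIGNED`. This is
  deliberate: the test cannot distinguish signal from composition there.
* **Ties.** Exact ties in adjusted p are broken by raw p, then label
  order, so assignments are deterministic.

## Spatial projection with shared-nearest-neighbour weights

A query cell `j` is projected to `R = sum_i r_i * theta_hat_i` over its
`K` nearest reference cells with positions `r_i`. The SNN weight
`theta_i` is not uniquely defined in the literature; here it is the
**Jaccard overlap** between the `k_graph`-nearest-neighbour sets of `j`
and of reference cell `i`, computed in the pooled (query + reference)
embedding — the convention used by the single-cell ecosystem's SNN graphs.
This is the largest interpretive decision in the module: any
neighbourhood-overlap measure would qualify as "shared nearest neighbour",
and results are only reported at the level of recovered spatial structure
(domain membership, centroid ordering), which is robust to the choice.

Defaults: `K = 10` reference neighbours, `k_graph = 20`. If all overlaps
are zero (a query cell far from the reference), the weights fall back to
uniform `1/K` and the cell is flagged rather than dropped — downstream
density summaries can then exclude flagged cells explicitly.

Since `theta_hat` lies in the simplex, `R` is always inside the convex
hull of the neighbour positions; the tests check this barycentrically.
Group densities are product-Gaussian KDEs with per-axis Silverman
bandwidth `sd * (4 / ((d + 2) n))^(1/(d + 4))`, `d = 3`; the bandwidth is
a visualisation choice, not an inferential one.

## Diffusion maps and pseudotime

The transition matrix uses an adaptive Gaussian kernel
`W_ij = exp(-d_ij^2 / (2 sigma_i sigma_j))` with `sigma_i` the distance to
the `ceiling(n_neighbors/2)`-th neighbour, supported on the symmetrised
`n_neighbors`-NN graph. Adaptive bandwidths keep the walk well-mixed in
regions of varying density, which differentiation time courses always
have. The spectrum is obtained from the symmetric conjugate
`D^{-1/2} W D^{-1/2}` (dense symmetric eigensolver — exact, deterministic,
and entirely adequate at the few-thousand-cell scales this package
addresses; an iterative solver would add a dependency without changing
any result at these sizes). The trivial constant eigenvector is dropped;
components are scaled by their eigenvalues. Pseudotime is the diffusion
distance to a root cell with the accumulated weighting
`lambda / (1 - lambda)` per component, truncated to the computed
components; the root defaults to the cell with minimal collection time.
A disconnected neighbourhood graph is an error that names the component
sizes — silently analysing disconnected pieces would make pseudotime
meaningless.

## Unbalanced entropic optimal transport

Between consecutive timepoints the coupling `gamma` minimises

```
<C, gamma> - epsilon * H(gamma)
  + lambda1 * KL(gamma 1 || a) + lambda2 * KL(gamma' 1 || b)
```

with squared-Euclidean cost `C` in the shared embedding, divided by its
median so that `epsilon` is scale-free. Defaults `lambda1 = 1`,
`lambda2 = 50`, `epsilon = 0.01` follow the lineage-tracing setting this
package implements: the weak source constraint lets populations grow or
shrink (mass creation/destruction), while the strong target constraint
anchors the observed composition at the later timepoint. Marginals
default to uniform (unit growth) — no proliferation prior is assumed —
with a hook (`a`, `b`) for per-cell growth weights.

The solver is a generalised Sinkhorn iteration with KL-relaxed marginals,
run in *stabilised* form: multiplicative scalings between BLAS
matrix-vector products, with the scalings periodically absorbed into
log-domain potentials (and a pure log-domain fallback on overflow), so
`epsilon = 0.01` on a median-normalised cost is numerically safe.
`lambda = Inf` gives exactly balanced Sinkhorn. Convergence is declared
when the log-domain scalings change by less than `tol` (default `1e-8`)
between sweeps; non-convergence within `max_iter` (default 5000) returns
the map with `converged = FALSE` and a warning, never silently.

### From couplings to a lineage graph

Couplings are aggregated cluster-to-cluster. The contribution matrix is
normalised **per target** by default (`normalize = "ancestors"`): entry
((c, i), (c', i+1)) is the fraction of cluster c''s mass at timepoint i+1
that was drawn from cluster c — each descendant's ancestry distribution,
which is the quantity "ancestor contributions to populations at subsequent
time points" describes. Under this reading a cluster with a single true
parent scores ~1 regardless of how many siblings share that parent, so
near-certain links survive the power threshold. The alternative row
normalisation (each source's descendant distribution,
`normalize = "descendants"`) is also implemented; note that under it a
parent splitting evenly into two children scores 0.5 per child and
`0.5^30` is always censored, so branching trees cannot survive the
default sparsification — a structural property, not a bug, and the reason
ancestors is the default.

Sparsification raises entries to the power `P = 30` and censors values
`<= 0.1`: `0.95^30 ~ 0.215` survives, `0.90^30 ~ 0.042` does not, i.e.
only contributions above ~0.926 are kept. Two readings of the
power-threshold rule are exposed: `mode = "powered"` (default) keeps the
powered values as edge weights; `mode = "masked"` uses the powered matrix
only as a sparsity mask and keeps the raw contributions. Both give the
same edge set; only downstream edge weights differ.

The directed KNN graph keeps each node's `k_graph = 5` strongest outgoing
links. Walktrap community detection (walk length 4) runs on the
symmetrised graph, because the random-walk agglomeration is defined for
undirected graphs; isolated nodes become singletons. Meta-clusters are
annotated with the lineage whose marker set has the highest mean logCP10k
expression over the constituent cells, with exact ties reported as
`UNRESOLVED`; labels propagate back to cells through cluster identity.

Ancestor queries (`ancestor_contributions`) pull a target set's mass back
through the chain with per-target (column-stochastic) normalisation,
which conserves total mass exactly at every step and reduces to the
source marginal when the target is everything. Maps between arbitrary
(non-consecutive) timepoint pairs can be computed directly with
`compute_transport_map` when a single-step ancestor query is preferred
over chaining.

## Preprocessing

`normalize_logcp10k` is the droplet standard: natural log of 1 + counts
scaled to 10,000 per cell (zero-total cells are flagged, not dropped).
HVG selection ranks genes by a binned dispersion z-score — variance of
the normalized values standardised by the *median and MAD* of variances
in 20 bins of similar mean. Robust bin moments matter: with mean/SD
moments, a bin rich in genuinely variable genes (exactly what planted
markers or strong biological programs produce) inflates its own baseline
and masks its members. PCA runs on centred, unit-variance-scaled HVG
columns via exact SVD with a fixed sign convention (largest-magnitude
loading positive), so embeddings are reproducible to the bit across
platforms. Defaults: 50 PCs for transport, 20 for neighbour graphs —
standard operating points for these two uses.

## The synthetic generator: what it emulates, and what it does not

`simulate_timecourse` plants a known lineage tree over a 10-point, 0–108 h
collection schedule: a pluripotent root; mesoderm-like and endoderm-like
branches splitting first; amnion-like and PGC-like lineages splitting
later from a shared progenitor. Counts are negative binomial with
`var = mu + alpha mu^2` (`alpha = 0.5`, droplet-scale overdispersion);
committed clusters carry a +1.5 natural-log shift on 50 planted marker
genes each (markers are drawn from a moderately-expressed baseline — a
marker with near-zero expression would be unobservable by construction);
100 genes follow a smooth temporal program. The ground-truth embedding is
generated *directly* in 10 dimensions (cluster trajectory centroid +
isotropic Gaussian jitter), decoupling the geometry the lineage methods
see from preprocessing correctness; the counts -> PCA route is exercised
separately (`analysis/02`, integration tests).

Two geometric regimes matter:

* **Discrete-cluster regime (the default)**: lineage separation 15 with
  jitter SD 0.25. This is the regime in which cluster identity is
  unambiguous latent truth — the analogue of well-integrated PC embeddings
  where germ layers form clearly separated clusters — and it is required
  for planted-tree recovery to be a fair benchmark: the `P = 30` power
  threshold keeps only ancestry fractions above ~0.926, and with weak
  source constraints (`lambda1 = 1`) the solver covers any local
  supply/demand imbalance (e.g. a progenitor whose two children jointly
  demand 1.5x its mass) partly by drawing ancestry from other lineages.
  At lower separation-to-jitter ratios (e.g. 6) that leakage reaches
  ~20% and genuine split edges fall below the survival threshold — a
  known, documented property of the method under mass imbalance, not an
  implementation artefact.
* **Continuum regime** (e.g. separation 4, jitter 1.5, as in
  `analysis/05`): branches overlap smoothly, which is what diffusion maps
  and pseudotime assume; the discrete regime disconnects the
  neighbourhood graph and is deliberately rejected by `diffusion_map`.

`simulate_spatial_reference` places reference cells on an ellipsoid shell
(semi-axes 100 x 50 x 50) with lineage domains as contiguous
anterior-posterior slabs; `plant_query` draws query cells from the same
per-lineage embedding distributions with held-out labels.

What the generator does **not** emulate: transcriptome-wide gene-gene
correlation, batch effects and integration artefacts, doublets, ambient
RNA, library-size variation beyond NB sampling, and gradual (rather than
step) divergence of committed states. Passing tests therefore demonstrate
correctness of the computations and recoverability under clean planted
structure — not robustness to the full messiness of real droplet data.

## Numerical conventions

* Exact distance ties in every KNN step break deterministically by lowest
  index; top-k edge selection ties break by target order.
* The MTX reader resolves orientation by matching dimensions to name-file
  lengths and refuses to guess when both orientations fit.
* Zero-overlap SNN weights, zero-count cells and unconverged transport
  maps are flagged, never silently repaired or dropped.
* Problem sizes used in the checked workflows — 6,400 cells, couplings up
  to 800 x 800, graphs of 32 nodes — were chosen so the whole study runs
  in minutes on one core; every component scales to a few thousand cells
  per timepoint with dense linear algebra.

## Known limitations

* Ancestry leakage under mass imbalance (above) bounds how sharp the
  `P = 30` sparsification can be on noisy, strongly unbalanced data.
* Per-cell growth weights are accepted but no growth estimation from
  proliferation signatures is provided.
* Dataset integration (alignment) is out of scope: embeddings are assumed
  pre-aligned; `pca_embed` provides a plain joint-PCA fallback only.
* Walktrap granularity is modularity-driven; long branches may split into
  several meta-clusters (harmless for annotation, which is per
  meta-cluster) and progenitor trunks carry no marker signal, so their
  annotation margin is reported and should be treated as low-confidence.
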