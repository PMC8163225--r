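---
title: "NetPCA and metabolic-network contextualization: models and methods"
author: "netpca package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NetPCA and metabolic-network contextualization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpca)
```

## The problem

Multi-cohort, multi-assay LC-MS metabolomics produces a *network of data
matrices* rather than one table: each cohort-timepoint (a *row class*,
e.g. samples drawn before a hemodialysis session) is measured on several
analytical blocks (a *column class*, e.g. the RPLC+ setup), and matrices
are linked whenever they share observations or share variables. Analyzing
the matrices separately breaks those links; naive concatenation ignores
the longitudinal and multi-assay structure. NetPCA keeps the links: it
extracts *global* components under the constraint that all matrices of a
row class share one score vector and all matrices of a column class share
one loading vector.

The motivating application is a chronic kidney disease (CKD) study
design: five cohorts spanning the severity range from healthy controls to
end-stage renal disease, with repeated sampling around hemodialysis,
kidney graft and kidney donation, measured on four LC-MS setups. The
package ships a synthetic generator for exactly that design, because the
original cohort data are not publicly deposited.

## The NetPCA model

Write $X_{gb}$ for the matrix of row class $g$ and column class $b$
(after unit-variance scaling, see below). Component $a$ solves

$$\min_{\{t_g\},\{p_b\}} \sum_{(g,b)} \lVert X_{gb} - t_g p_b^\top \rVert_F^2
\quad \text{s.t.} \quad \sum_b \lVert p_b \rVert^2 = 1,$$

so one score vector $t_g$ serves every matrix in row class $g$ and one
loading vector $p_b$ serves every matrix in column class $b$ — the
shared-row and shared-column links of the incidence structure become the
constraints of the decomposition. The alternating least squares updates
are

$$t_g \leftarrow \frac{\sum_b X_{gb} p_b}{\sum_b \lVert p_b\rVert^2},
\qquad
p_b \leftarrow \frac{\sum_g X_{gb}^\top t_g}{\sum_g \lVert t_g\rVert^2},$$

followed by global renormalization of the concatenated loading, with the
norm pushed into the scores so that scores carry the variance. After
convergence each matrix is deflated by its fitted rank-one term and the
next component is extracted from the residuals.

Properties that follow (and that the test suite asserts):

* On a single-matrix network the procedure *is* PCA: scores and loadings
  equal the leading singular triplets, and the multi-component
  reconstruction error equals that of the truncated SVD.
* A noiseless rank-one network is recovered exactly, with 100% of the
  variance on component 1.
* Because deflation uses the score/loading pair produced by the last
  loading update, the residual is exactly orthogonal to the scores; the
  variance bookkeeping identity (total = fitted + residual sums of
  squares) and the orthogonality of successive concatenated score vectors
  hold to machine precision on fully crossed networks, not merely to the
  convergence tolerance. Orthogonality holds for the *concatenated*
  scores; restricted to a single row class, score vectors of successive
  components are in general slightly correlated, exactly as PCA scores
  restricted to a subgroup are.

Two variance decompositions support interpretation. The *block
influence* of matrix $(g,b)$ on component $a$ is
$\lVert t_{ga} p_{ba}^\top\rVert_F^2$ normalized to 100 per component: an
objective measure of which cohort/assay combinations drive each global
trend. The *metabolite-centric* view reports, per variable, the percent
of that variable's own (scaled) variance explained by each component;
`select_markers()` shortlists the variables at or above a threshold,
default 20% (inclusive), ordered by descending percent with ties broken
by variable id.

## Design choices in the fit

* **Objective.** A least-squares consensus formulation was chosen; it
  yields shared loadings per block, shared scores per observation set,
  global components, and a well-defined per-matrix variance split, and it
  degenerates to PCA on a single matrix. A covariance-maximizing variant
  would share these qualitative properties but not the exact SVD
  equivalence used as an oracle.
* **Scaling scope.** `uv_scale()` computes each variable's mean and
  sample (n−1) standard deviation over the concatenation of *all*
  observations sharing that variable, across groups and timepoints.
  Per-matrix centering would annihilate between-group mean differences —
  the very signal the leading component should carry. Whether a
  reference-group-only scaling would be preferable is not decidable from
  the application; the global pool is the package's convention.
* **Initialization.** Block loadings start at the leading right singular
  vector of the row-wise concatenation of each column class (the natural
  warm start, deterministic); `init = "random"` with a seed exists for
  robustness checks.
* **Convergence.** Relative objective change below `tol` (default 1e-9),
  `max_iter` 500; an exactly-fitted component (objective negligible
  against the total sum of squares) also counts as converged.
  Desk-scale problems converge in tens of iterations.
* **Sign.** Each component is flipped so its largest-magnitude loading
  entry is positive, fixing the orientation of score plots.
* **Weighting.** Unequal group sizes are not reweighted; every
  observation contributes equally.
* **Missing values** are not supported in the fit; the QC preprocessing
  is expected to have removed or imputed them upstream.

## QC preprocessing

`qc_ratio_filter()` implements reliability filtering from pooled QC and
diluted QC (dQC) injections: per feature, dQC/QC intensity ratios are
formed over adjacent dQC–QC pairs; a feature is kept iff the ratio
series' relative standard deviation is at most 50% *and* the median
ratio lies in [0.2, 0.8]. The RSD is read as applying to the ratio
series (not to the dQC intensities alone; the alternative reading would
ignore the pairing that makes the dilution informative). The dilution
factor itself is treated as encoded in the ratio window; the median is
used as the point estimate because single outlier injections should not
discard a feature.

`loess_normalize()` corrects intensity drift: per feature and batch, a
degree-1 LOESS of QC intensity on injection order (span 0.75 by default;
the span is configurable because no single value suits all QC spacings)
gives a drift curve; intensities are divided by the curve and rescaled to
the batch QC median, then batches are equalized to the global QC median.
Boundary injections reuse the nearest fitted value rather than
extrapolating; with fewer than four usable QCs the local regression falls
back to a straight line. A configurable `burn_in` excludes
system-conditioning injections at the start of each batch from drift
fitting (default 0, since the synthetic runs contain none).

## Enrichment conventions

`map_identifiers()` matches queries to network nodes by normalized exact
match (case-fold, trim, strip a trailing compartment suffix), trying node
id, then display name, then external ids — first hit wins, so mapping is
deterministic. `ora()` tests each pathway with the right-tailed
hypergeometric law (equivalently the right-tailed Fisher exact test);
q-values are Benjamini–Hochberg across all pathways with at least one
member in the universe (empty pathways are skipped rather than diluting
the FDR denominator). The universe is *all* metabolites of the network
after compartment collapse, not only the mapped queries — the
network-wide background convention; selections restricted to markers make
the test answer "is this pathway over-represented among my markers
relative to the whole metabolome I could have hit". Reported
$-\log_{10}$ values are rounded to 3 decimals, which pins the 5%
threshold at 1.301 and makes "significant at $q \le 0.05$" coincide with
"displayed value $\ge 1.301$".

## Compound-graph topology

The compound graph joins two metabolites when they are substrate and
product of the same reaction; reversibility is ignored (undirected
edges), since path mining does not orient reactions. Compartment copies
(`atp_c`, `atp_m`, ...) are collapsed to one node; transport self-loops
vanish and parallel edges from distinct reactions merge, transferring
carbon if any contributing reaction does. Ubiquitous side compounds
(water, CO2, redox and energy cofactors and their deoxy counterparts; the
shipped list is deliberately user-overridable because no canonical
complete list exists) are removed, and edges without carbon transfer are
pruned, before any path is computed.

The *lightest path* between two metabolites minimizes the sum of squared
node degrees over the path, **endpoints included** — the inclusive
convention was chosen because excluding endpoints would make the
self-distance convention awkward and would let hub endpoints distort
comparisons; self-distance is 0 so the matrix is a valid dissimilarity.
Degrees are those of the graph *after* filtering, which matters: removing
a side compound can change which route is lightest. Ties resolve to fewer
nodes, then to the lexicographically smallest node sequence, making
subnetworks reproducible. The search is a Dijkstra with node weights
(entering node $v$ costs $\deg(v)^2$, the source's weight added once);
the test suite checks it against exhaustive simple-path enumeration and
against an independent igraph edge-weight reformulation.

Pairwise lightest-path costs over a metabolite subset form the distance
matrix for module detection. Disconnected pairs receive the sentinel
$2 \times$ (largest finite entry) — under complete linkage this forces
disconnected components to merge last, approximating clustering the
components separately while keeping a single tree; all sentinel pairs are
flagged, and `module_report()` warns when a module's cohesion rests on
them.

## Module clustering

Complete linkage (maximum inter-cluster distance) is the default and only
wired-in linkage: it favours compact clusters and avoids the chaining
effect that single linkage would introduce on path distances. Leaves are
sorted by id before agglomeration so ties resolve deterministically. The
number of modules `k` is a user parameter — the motivating analysis chose
its module count by visual inspection of the dendrogram, which is not
automatable — and `silhouette_profile()` reports mean silhouette widths
over a k range as explicit guidance. Note that on chain-like pathway
graphs the silhouette can prefer very small k even when the planted
partition is recovered perfectly at the planted k; the profile is
guidance, not an estimator.

## What the synthetic generators emulate — and what they do not

`ckd_design()` + `generate_cohort()` reproduce the study *structure*: 10
row classes (56 CTRL, 69 ICKD, 35 HD×2, 42 KG×3, 24 DV×3 = 393 profiles),
4 blocks (88 + 38 + 27 + 65 = 218 variables), 40 matrices, 240
shared-row/shared-column links. Two planted axes drive the signal: a
severity covariate ordered CTRL ≈ preDV < ICKD < preHD ≈ preKG with
post-treatment classes pulled back toward intermediate levels, and a
dialysis-specific covariate shifting postHD only. Both enter as rank-one
mean shifts shared across blocks, plus independent Gaussian noise
(sd 1) — the simplest structure the NetPCA model assumes. Severity
amplitudes are drawn uniformly in [0.5, 1.5] on half the variables;
the dialysis axis touches 30 variables with amplitudes in [0.8, 1.5].
These are free parameters chosen to give a clearly dominant first axis
and a small second axis; the true effect sizes of the motivating study
are unknowable without its data, so the generator's component-variance
percentages are not calibrated to any published value. Real LC-MS data
additionally show heteroscedastic, heavy-tailed noise, correlated
metabolites, within-subject correlation across timepoints (an optional
subject-level random effect is available but off by default, since the
model does not exploit it) and missingness — passing recovery tests on
the generator therefore demonstrates correctness of the machinery, not
performance on real cohorts.

`toy_network_design()` + `generate_toy_network()` build a
pathway-annotated compound graph at test scale: 5 pathways of 8
metabolites wired as carbon-transfer chains, bridges where one pathway's
end product feeds the next pathway, 2 high-degree side-compound hubs
named after real currency metabolites, and 15% extra non-carbon edges.
Pathway membership is the planted module truth. A genome-scale
reconstruction is orders of magnitude larger and less regular; the toy
network exercises every topological operation but does not emulate
realistic degree distributions.

## Problem sizes and numerical tolerances

The test suite and the acceptance script run the full cohort design (393
× 218), the 40-node toy network, brute-force path enumeration on graphs
of up to 8 nodes, exhaustive hypergeometric enumeration for universes up
to 12, and direct max-linkage recomputation up to 7 leaves — sizes at
which the independent oracles are exact and fast. Numerical tolerances:
scaling idempotency 1e-10; SVD equivalence 1e-8 relative; influence sums
1e-6; ALS default `tol` 1e-9 (tests that assert machine-precision
identities tighten it to 1e-13).

## Known limitations

* Incomplete networks (missing row-class/column-class combinations) are
  fitted by the same masked updates, but the exact orthogonality and
  bookkeeping identities then hold only approximately.
* No supervised variants, confidence regions, or cross-validation of the
  component count.
* `map_identifiers()` is exact-match only; fuzzy or synonym-table
  matching is out of scope.
* The pipeline's subnetwork stage needs at least two mapped markers in
  significant pathways; otherwise the network stages are skipped with a
  logged notice.
* Atom mappings are consumed as precomputed edge flags; the package never
  computes carbon transfer itself.

## A worked end-to-end run

```{r pipeline, eval = FALSE}
sim <- generate_cohort(ckd_design(), seed = 42)
all_vars <- names(sim$truth$severity_amplitude)
ids <- c(sim$truth$severity_vars[1:8],
         setdiff(all_vars, sim$truth$severity_vars)[1:32])
toy <- generate_toy_network(toy_network_design(metabolite_ids = ids),
                            seed = 11)
cfg <- pipeline_config(sim$network, toy$graph, k = 3, seed = 42)
bundle <- run_pipeline(cfg)
summary(bundle$model)
bundle$ora
make_figures(bundle)
```

The severity support is planted inside pathway `PW1` of the toy network,
so `PW1` tops the enrichment table and seeds the subnetwork whose
distance matrix is clustered into modules; the run directory then holds
every exported table plus the run log.
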