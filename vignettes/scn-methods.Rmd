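---
title: "Structural covariance network analysis with scnet: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural covariance network analysis with scnet: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

A structural covariance network (SCN) is a group-level graph: nodes are
atlas regions, and the edge weight between regions $i$ and $j$ is the
Pearson correlation $r_{ij}$, across the subjects of one group, of their
region-averaged cortical thickness after removing a linear age effect.
Unlike tractography or functional connectivity, the network does not exist
per subject; it is a property of the cohort, which is why group comparison
requires relabelling subjects and rebuilding the whole matrix (see
*Permutation inference* below).

`scnet` implements the full chain:

1. **Age adjustment** (`residualizeAge`): each region column is replaced by
   the residuals of an ordinary least-squares fit on intercept + age.
   Residuals are exactly mean-zero and uncorrelated with age. With a
   constant age column the fit is degenerate; the table is mean-centred
   instead and a warning is raised. By default adjustment happens within
   each group separately, matching per-group matrix construction; a pooled
   mode (`residualize = "pooled"`) is exposed because the literature is
   split on this choice.
2. **Association matrix** (`associationMatrix`): the region-by-region
   Pearson matrix $M$ with its diagonal forced to zero.
3. **Density thresholding** (`thresholdByDensity`, `densitySweep`): at
   density $D$ the $K = \mathrm{round}(D\,n(n-1)/2)$ largest correlations
   become the edges of a binary undirected graph $A$. Matching $K$ between
   groups is what makes their topology comparable; an absolute cutoff
   ($a_{ij} = 1$ iff $r_{ij} > r_0$, `thresholdAbsolute`) is provided as a
   secondary operation but yields group networks of different size, so the
   primary pipeline never uses it.
4. **Graph metrics** (`globalMetrics` and friends): clustering coefficient,
   characteristic path length, global and local efficiency, transitivity,
   modularity, degree, betweenness, and the rewired-null normalized
   $\gamma$, $\lambda$, $\sigma = \gamma/\lambda$.
5. **Permutation inference** (`permutationTest`) per density and on the
   area under the metric-versus-density curve (AUC), with
   Benjamini-Hochberg FDR across regions for nodal metrics.
6. **Hub identification** (`identifyHubs`): regions whose betweenness is at
   least $\bar b + 2\,\mathrm{sd}(b)$.

# The density sweep

The default grid runs from 0.1 to 0.5 in steps of 0.02 (21 points,
`densityGrid()`). Below roughly 0.1 group networks tend to fragment;
above 0.5, binary cortical networks are generally considered
non-biological. The sweep is cut from a single edge ranking, so edge sets
are exactly nested along the grid, and the comparison range starts at
`minUnfragmentedDensity` ($D_{\min}$), the smallest grid density at which
*both* group networks are connected. Hub analysis defaults to $D_{\min}$.

Numerical conventions, chosen for bit-exact reproducibility across
platforms:

* $K$ uses round-half-away-from-zero (R's `round` is half-to-even).
* Ties at the density cut break toward the lexicographically smaller
  region pair.
* Edges are ranked by signed correlation, so negative correlations enter
  only after all positive ones; ranking by magnitude is available via
  `rankBy = "absolute"`.

# Metric definitions and their edge cases

All metrics operate on binary undirected graphs and, with one exception,
are computed by igraph. Conventions:

* **Clustering** $C_i$: fraction of realized edges among neighbours; 0
  when the degree is below 2. Network value is the node mean.
* **Path length** $L_p$: mean shortest path over *reachable* pairs.
  Unreachable pairs are excluded and counted in a message; this is a
  safeguard, since the sweep starts at a connectivity-checked $D_{\min}$.
* **Global efficiency**: mean of $1/d_{ij}$ with unreachable pairs
  contributing 0.
* **Local efficiency** of node $i$: global efficiency of the subgraph
  *induced by the neighbours of* $i$, 0 below degree 2. igraph's
  `local_efficiency()` implements a different published variant in which
  paths may leave the neighbourhood, so this metric is computed directly
  on the adjacency matrix via boolean-product BFS.
* **Transitivity**: $3 \times$ triangles / connected triples; defined as 0
  on triple-free graphs.
* **Betweenness**: Brandes pair-fraction accumulation, endpoints excluded,
  *unnormalized*. Any positive rescaling cancels both in the hub z-rule
  and in permutation differences of mean-normalized nodal values, which is
  exercised by a scale-invariance test.
* **Modularity** $Q$: exact maximization is NP-hard. Graphs with at most 8
  nodes are solved exactly by exhaustive enumeration of set partitions;
  larger graphs use seeded multi-restart Louvain agglomeration whose best
  partition is then polished by greedy single-node moves and community
  merges (delta-$Q$ updates). Identical seeds give identical partitions.
* **Small-world indices**: $\gamma$ and $\lambda$ divide $C_p$ and $L_p$
  by their means over `nRandom = 20` Maslov-Sneppen degree-preserving
  rewirings (10 attempted swaps per edge, connectivity re-checked with
  retries when the input was connected). Both knobs are exposed; 20/10 is
  common practice and keeps the variance of the null means well below the
  group differences of interest.
* **Nodal normalization**: nodal values are divided by their network mean
  (mean-1 convention). The within-network affine freedom of "normalized"
  regional measures cancels in between-group comparisons only under this
  convention, which is why it is the package default.

# Permutation inference

The observed statistic is the groupA $-$ groupB difference (groups in
sorted label order) of a metric evaluated through the *entire* pipeline.
Each of the `nPerm` permutations reassigns subject group labels (group
sizes preserved) and re-runs residualization, correlation, thresholding
and metric evaluation, so the null distribution carries the full
uncertainty of group-level covariance estimation. Two-tailed p-values use
the small-sample correction $(1 + \#\{|t^\ast| \ge |t|\})/(n_{perm}+1)$,
which cannot reach 0 and guarantees validity; 2.5/97.5 null percentile
bounds are stored so results can be displayed as difference curves with
confidence bands, while decisions are made on p-values. For nodal metrics
BH-FDR is applied across the regions, separately per density and for the
AUC - the narrowest family consistent with per-metric regional reporting.
The default `nPerm = 1000` follows standard practice; the test suite uses
100-200 with fixed seeds.

AUC over the density grid (trapezoidal rule) is the threshold-free
summary. It is linear, so the AUC of a difference curve equals the
difference of AUCs; the suite asserts this to $10^{-12}$.

# The synthetic cohort generator

No subject-level imaging data are distributable, so `generateCohort`
simulates thickness tables from a linear factor model:

$$t_{sr} = \mu_r + \beta_r\,\mathrm{age}_s + \sum_k L_{rk} f_{sk} +
\varepsilon_{sr},$$

with standard-normal factor scores, Gaussian noise, and age drawn from a
normal truncated to [18, 60] years. Within a group the implied covariance
of two regions is $(LL^\top)_{ij} + \sigma^2 1[i=j]$ plus the age-induced
term $\beta_i \beta_j \mathrm{Var}(\mathrm{age})$, so population
correlations are controlled in closed form and tests can verify sample
estimates against them.

Three canned configurations define the study conditions:

* `nullConfig`: two groups of 23 subjects (the study size) on the
  68-region Desikan-Killiany atlas; one weak global factor (loading
  0.06 mm on every region) plus four *homotopic* community factors
  (0.07 mm) - left/right counterpart regions share a community, echoing
  the strong homotopic covariance of real SCN matrices - with 0.10 mm
  noise, region means 2.2-2.8 mm and thinning slopes of $-0.005$ mm/year.
  This yields moderate correlations (within-community about 0.46, between
  about 0.20) typical of thickness SCNs. Both groups share all
  parameters, so labels are exchangeable: the reference for type-I-error
  experiments.
* `effectConfig`: group B's community loadings are shrunk (50% by
  default) with its global loading boosted to preserve per-region signal
  variance. Covariance homogeneity rises, so at matched density group B's
  network spreads edges nearly uniformly - more integrated, less modular -
  while group A keeps its community concentration. This planted contrast
  is reliably detected by the global-efficiency AUC test at
  $n = 100$/group.
* `hubConfig`: eight homotopic communities (member loading 0.12 mm,
  noise 0.045 mm, within-community correlation about 0.88) and one chosen
  region loading 0.045 mm on *every* factor. Its correlation with each
  community (about 0.31) exceeds the zero between-community correlation,
  so after thresholding it is the main bridge between communities and its
  betweenness dwarfs the network: the planted hub for end-to-end recovery
  tests.

What the generator does **not** emulate: realistic spatial thickness maps,
scanner/site effects, non-Gaussian morphometry, or subject-level
covariance (an SCN has none). Passing tests therefore demonstrate that the
pipeline recovers known covariance topology under its own generative
assumptions - not that any particular clinical contrast is reproducible.

One master seed drives age, factor scores and noise through independently
seeded substreams, so cohorts are bit-reproducible and components can be
varied independently.

# Design choices that were genuinely open

* **Residualization scope**: per group (default) versus pooled - both
  provided; per group matches per-group matrix construction.
* **Population vs sample SD in the hub rule**: population (divide by $n$)
  by default, because the atlas node set is a census, not a sample; the
  sample form is one keyword away (`sdType = "sample"`), and the inclusive
  "$\ge$" comparison follows the "at least 2 SD" phrasing.
* **Pooled-variance t-test** for summary demographics: with the printed
  group summaries (42.04 ± 10.52 vs 36.96 ± 6.23, $n = 23$ each) the
  pooled test gives $p = 0.0525$; Welch gives $0.0539$. Only the pooled
  variant pins the conventionally reported 0.052 at printed precision.
* **Which surface weights region averages used upstream** (area-weighted
  or not) is invisible to this package: it consumes already-averaged
  values and takes no position.
* **FDR family**: across the 68 regions, separately per metric and per
  summary - the narrowest family consistent with per-metric regional
  tables.

# Problem sizes used by the test suite

Simulation sizes are stated in each test: type-I error uses 100 null
replicates at 200 permutations each (the binomial 95% interval around the
nominal 0.05 at 100 replicates is [0.013, 0.107]); power uses 20
replicates of the planted contrast at $n = 100$/group; hub recovery uses
20 seeds at $n = 200$/group; metric-oracle equivalence uses 100 seeded
random graphs of 5-8 nodes, where Floyd-Warshall distances,
triangle/triple enumeration, exhaustive shortest-path enumeration and
exhaustive partition search are all feasible as independent oracles.

# Known limitations

* Binary undirected graphs only: no weighted, directed, rich-club or
  motif analyses.
* No shrinkage or robust covariance estimation; with 23 subjects the
  correlation estimates are noisy, which the permutation null reflects
  but an analytic null would not.
* Modularity above 8 nodes is a polished heuristic; only the small-graph
  branch is provably exact.
* The permutation test assumes exchangeability of subjects under the
  null; confounds beyond age (sex, site, scanner) must be handled before
  the data enter the pipeline.

# A minimal session

```{r, eval = FALSE}
library(scnet)
dk <- builtinAtlas("desikan_killiany_68")
te <- generateCohort(nullConfig(dk, seed = 1))

labels <- groupLabels(te)
mA <- associationMatrix(te[, labels == "groupA"])
mB <- associationMatrix(te[, labels == "groupB"])
dmin <- minUnfragmentedDensity(mA, mB)

globalMetrics(thresholdByDensity(mA, dmin))
permutationTest(te, "global_efficiency", nPerm = 1000, seed = 2)
identifyHubs(thresholdByDensity(mA, dmin), group = "groupA")

# or, end to end with a written report bundle:
res <- runSCNPipeline(te, "scn_out", nPerm = 1000, seed = 2)
```
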