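---
title: "Methods: diffusion-kurtosis brain networks in dknet"
author: "dknet maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diffusion-kurtosis brain networks in dknet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dknet)
```

## The analysis this package implements

Diffusion kurtosis imaging (DKI) quantifies non-Gaussian water diffusion
and yields, per atlas region, a set of scalar metrics: the kurtosis family
(MK, AK, RK, KFA) and the tensor family (MD, FA, Ad, RD). `dknet`
implements the network analysis that turns such regional metrics into
graph-theoretical statements about a two-group study (typically a patient
cohort against matched controls):

1. **Grey-matter (GM) structural-covariance networks.** For one metric and
   one group, the 90-region correlation matrix is the Pearson correlation,
   across subjects, of regional values between every pair of regions
   (`gm_correlation_matrix()`).
2. **White-matter (WM) networks.** Per subject, tractography defines an
   edge wherever at least `fn_min` streamlines connect two regions; edge
   weights are the fiber number (FN), mean fiber length, or the mean of a
   diffusion/kurtosis metric along the tract (`wm_edge_matrices()`).
3. **Sparsity thresholding.** Each connectivity matrix is cut to a fixed
   edge budget `K = floor(S * N(N-1)/2)` over a sweep `S = 6%..40%`
   (`threshold_by_sparsity()`, `sparsity_sweep()`).
4. **Topology.** Clustering coefficient `Cp`, characteristic path length
   `Lp`, global/local efficiency `Eg`/`Eloc`, and betweenness `Bi`
   (`network_metrics()`); small-worldness `gamma = Cp/mean(Cprand)`,
   `lambda = Lp/mean(Lprand)`, `sigma = gamma/lambda` against an ensemble
   of degree-preserving rewired null networks (`small_worldness()`).
5. **Hubs.** Normalised betweenness `bi = Bi/B` with the conventional
   strict cutoff `bi > 1.5` (`identify_hubs()`).
6. **Inference.** A label-permutation test that reruns the whole GM
   pipeline per permutation (`gm_permutation_test()`); ANCOVA with age and
   sex covariates for subject-level WM attributes
   (`ancova_group_effect()`); partial correlations between network
   attributes and cognitive scores (`partial_correlation()`);
   Benjamini-Hochberg correction by default (`adjust_pvalues()`).

Everything upstream of the regional tables and tract matrices — image
acquisition, tensor/kurtosis fitting, parcellation, voxel averaging,
tractography — is out of scope; inputs arrive as plain-text tables.

## Definitions and numerical conventions

* **Clustering.** Binary graphs: fraction of a node's neighbour pairs that
  are connected; degree < 2 scores 0; `Cp` is the unweighted mean over all
  nodes. Weighted graphs default to the Onnela geometric-mean form with
  weights scaled by the network maximum; a topology-only option exists.
* **Paths.** Weighted graphs use distance `1/weight`. `Lp` averages over
  *finite* pairs only and reports the number of excluded disconnected
  pairs; at 6% sparsity disconnected components are common, so this
  convention is unavoidable and is surfaced in the output metadata. An
  alternative is to analyse the largest component only; the finite-pair
  convention keeps the node set fixed across the sweep.
* **Efficiency.** The standard inverse-distance (Latora–Marchiori) forms:
  `Eg` is the mean of `1/d(i,j)` with `1/Inf = 0`; `Eloc` averages the
  global efficiency of each node's neighbour-induced subgraph.
* **Betweenness.** Pair-fractional, endpoints excluded, unnormalised.
* **Thresholding.** Correlation matrices rank edges by `|r|` (negative
  correlations are kept by magnitude; a positive-only switch exists),
  other matrices by raw weight. The edge count is exact; ties at the
  cutoff break by lexicographic node order so edge sets are reproducible,
  and sweep edge sets are nested.
* **Null networks.** Degree-preserving double-edge swaps (10 x edge count
  swap attempts per sample) are the default null model — matched random
  networks in the strong sense; an Erdős–Rényi option (same node and edge
  count only) is available. `Cprand`/`Lprand` are ensemble means
  (default `n_rand = 100`). Weighted nulls keep the weight multiset,
  shuffled over the rewired edges.
* **Small-world classification.** `sigma > 1` is the primary classifier; a
  strict variant (`gamma > 1` and `|lambda - 1| <= 0.25`) is also
  reported. If `Cprand = 0` the result is flagged not-evaluable rather
  than infinite.
* **Permutation test.** Group labels are shuffled preserving group sizes
  (21/19 by default); each permutation recomputes correlation matrix,
  threshold and metrics; the two-tailed p is `(1 + #{|null| >=
  |obs|})/(n_perm + 1)`, never exactly zero. Significant sparsities are
  reported as maximal contiguous runs with `p < alpha`.
* **Graph mode for GM inference.** The permutation pipeline defaults to
  *weighted* thresholded graphs (weights `|r|`): thresholding to a
  weighted matrix at the study sparsity is the convention this analysis
  family follows, and binary path length degenerates at high sparsity
  (almost all non-adjacent pairs sit at distance 2, so `Lp ~ 2 - S`
  carries no group signal). The descriptive small-world sweep defaults to
  binary graphs, classical structural-covariance practice; both modes are
  exposed everywhere.
* **ANCOVA.** `value ~ group + age + sex`, with the partial (type-II) F
  for the group term; constant covariates are dropped with a message,
  genuinely collinear designs are an error. Without covariates the F is
  exactly the squared pooled t statistic.
* **Partial correlation.** Residual-based, `t` reference with `n - k - 2`
  degrees of freedom; degenerate residual variance flags the result
  not-evaluable instead of returning a number.
* **Normality check.** One-sample Kolmogorov–Smirnov against a normal with
  the sample mean and SD. Estimating the parameters from the same sample
  makes the test conservative; the output carries that note.
* **Multiplicity.** The attribute tables correct across the ten metric
  columns within each attribute row (Benjamini–Hochberg by default;
  Bonferroni and none available).

## The synthetic cohort generator

No imaging data ship with the package; `cohort_config()` plus the
`generate_*` functions produce a synthetic study whose ground truth is
known, so every downstream stage is testable end to end. The generator's
defaults are the study conditions the package is validated under: 21
patients vs 19 controls, 90 regions, `gm_effect = 0.5`,
`wm_effect = 0.3`.

* **Latent control network.** A Watts–Strogatz ring lattice on 90 nodes
  (strides 1–3, i.e. 6 neighbours; rewiring probability 0.1). This is a
  genuinely small-world ground truth (high clustering, short paths).
* **Target correlation.** `R = cov2cor((I + aA)(I + aA)')` with coupling
  `a = 0.5`, the correlation of a network-coupled Gaussian `X = (I + aA)Z`.
  This is positive semidefinite by construction; latent edges carry the
  strongest entries (~0.6–0.8), pairs two steps apart carry weaker ones
  (<= ~0.3), everything else is exactly zero, so thresholding the target
  at the latent edge count recovers (nearly all of) the latent graph.
* **Patient perturbation.** Every off-diagonal entry between nodes that
  share at least one common neighbour in the latent graph — the
  within-cluster pairs: triangle edges and two-path pairs, but not
  between-cluster shortcuts — is scaled by `1 - gm_effect`. Patients thus
  lose local correlation coherence while long-range coordination
  survives, which reproduces the degraded small-world phenotype (lower
  weighted clustering, longer weighted paths) as a tunable truth. If a
  perturbation ever leaves the positive-semidefinite cone the matrix is
  repaired by eigenvalue flooring with a warning.
* **Observation model.** Regional values are log-normal:
  `log X = log(scale_m) + 0.2 L z + noise_sd eps` with `L` the Cholesky
  factor of the group target, so values are strictly positive and
  correlations are approximately preserved (the log-scale signal SD 0.2
  keeps the exponential distortion of Pearson correlations under ~1%).
  Metric scales are conventional magnitudes (MK 0.9, KFA 0.3, MD 0.9
  um^2/ms, FA 0.35, ...), config-exposed: the source study reports no
  value distributions, so these are *not* claims about real data.
* **White matter.** Patient latent topology is a degree-preserving
  rewiring of a fraction `wm_effect` of the control edges; FN counts are
  negative-binomial (size 5, mean 30) on latent edges with a 0.5% false-
  edge rate (FN 1–2); per-edge metric weights are log-normal around the
  metric scale, attenuated by `1 - wm_effect` in patients and scaled by
  `exp(0.15 * integrity)` per subject.
* **Covariates.** A per-subject integrity factor (N(0, 0.3), shifted down
  by `gm_effect + wm_effect` in patients) ties the network strength to
  cognition: MMSE and MoCA are linear in integrity (slope
  `cognition_link`, default 12 points per unit) plus noise, clipped to
  0–30. Ages follow typical late-onset demographics; sex counts are fixed
  at 12F/9M vs 9F/10M.
* **Reproducibility.** One master seed; every sub-generator derives a
  deterministic child seed, so the same config regenerates byte-identical
  outputs and any one component can be regenerated alone.

What the generator does **not** emulate: between-metric correlations
within a subject, spatially structured (autocorrelated) noise, site or
scanner effects, atrophy-driven registration error, and realistic
streamline-count dispersion. Passing the validation suite therefore
demonstrates that the pipeline recovers the truth *of this generative
family*, not that any particular clinical result is correct.

## Validation choices and problem sizes

The test suite validates the package at sizes chosen to exercise the
statistics without waste:

* Metric implementations are checked against an independent brute-force
  oracle (Floyd–Warshall distances, direct neighbour-pair counting,
  exhaustive shortest-path enumeration) on *all* non-isomorphic simple
  graphs with up to 6 nodes, 300 random 7-node graphs across densities,
  and 200 random weighted graphs with up to 12 nodes.
* Small-world sanity uses 90-node Watts–Strogatz graphs across densities
  matched to the 6–40% sparsity range (sigma > 1 in every run) and
  density-matched Erdős–Rényi graphs (ensemble-mean sigma within 0.15 of
  1).
* The permutation pipeline's type-I error is measured on 200 null cohorts
  (no injected effect) at sparsity 0.20 with `n_perm = 200` and must sit
  inside the exact binomial 95% interval around 0.05.
* Effect recovery runs the full pipeline on 50 cohorts at the default
  effect sizes and cohort sizes over a 9-point sparsity grid
  (`0.06–0.38`, step 0.04, `n_perm = 99`): at least 80% of runs must show
  decreased clustering *and* increased path length with `p < 0.05` over
  the majority of the grid.
* Determinism is checked through MD5 manifests of two identically seeded
  end-to-end runs.

## Known limitations

* GM inference operates on group-level correlation networks (the
  correlation construction requires it), WM inference on subject-level
  networks (ANCOVA requires it); the package makes that split explicit.
* The hub cutoff `bi > 1.5` and the sparsity bounds are conventions, not
  estimates; both are parameters.
* The weighted null model rewires topology and shuffles weights; it does
  not preserve weight–degree correlations.
* The Kolmogorov–Smirnov normality p-values are conservative with
  estimated parameters; treat them as screening, not confirmatory.
* Very sparse graphs can be disconnected; all path statistics then refer
  to the finite pairs, and the outputs say how many pairs were excluded.
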