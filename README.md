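# dknet — diffusion kurtosis brain networks

`dknet` is an R package for graph-theoretical analysis of brain networks
built from regional diffusion kurtosis imaging (DKI) metrics, aimed at
two-group neuroimaging studies (e.g. a dementia cohort against matched
controls). It covers both network families such studies use:

* **Grey-matter structural-covariance networks** — for one metric (MK, AK,
  RK, KFA, MD, FA, Ad, RD) and one group, edges are Pearson correlations
  of regional values across subjects;
* **White-matter tract networks** — per subject, edges are defined by
  tractography streamline counts (FN) and weighted by FN, mean fiber
  length, or mean diffusion/kurtosis metrics along the tract.

Matrices are thresholded to an exact edge budget over a sparsity sweep
(6–40%), and characterised by clustering coefficient `Cp`, characteristic
path length `Lp`, global and local efficiency `Eg`/`Eloc`, betweenness
`Bi`, and small-worldness against degree-preserving rewired null
ensembles:

```
gamma = Cp / mean(Cprand)    lambda = Lp / mean(Lprand)    sigma = gamma / lambda
```

with `sigma > 1` indicating small-world organisation. Hubs are regions
with normalised betweenness `bi = Bi / B > 1.5`. Group inference uses a
label-permutation test that reruns the whole correlation-network pipeline
per permutation, ANCOVA (age and sex covariates) for subject-level
white-matter attributes, and partial correlations with cognitive scores
(MMSE, MoCA), with Benjamini–Hochberg correction.

A synthetic cohort generator (`cohort_config()`, `generate_gm_cohort()`,
`generate_wm_cohort()`, `generate_covariates()`) produces a complete
two-group study with known ground truth — a small-world latent network,
a tunable patient perturbation, and cognition tied to network integrity —
so the entire pipeline is testable without any imaging data. See the
methods vignette (`vignettes/dknet-methods.Rmd`) for the model and every
numerical convention.

## Worked example

```r
library(dknet)

# a synthetic 21-patient / 19-control study, 90 regions
cfg <- cohort_config(seed = 1, metrics = "MK")
co  <- generate_gm_cohort(cfg)

# control-group MK correlation network at 10% sparsity
cm <- gm_correlation_matrix(co$tables$MK$controls)
tg <- threshold_by_sparsity(cm, 0.10, mode = "binary")
small_worldness(tg, n_rand = 100, seed = 2)
#> <small_world_result> gamma 3.573  lambda 1.104  sigma 3.237  (small-world, n_rand 100)

# group comparison over the sparsity sweep (weighted pipeline)
pt <- gm_permutation_test(co$tables$MK$patients, co$tables$MK$controls,
                          grid = seq(0.06, 0.40, 0.02), n_perm = 200, seed = 3)
pt
#> <permutation_result> 200 permutations, 18 sparsities (weighted graphs)
#>   Cp: significant (p<0.05) at 6%<=S<=40%
#>   Lp: significant (p<0.05) at 10%<=S<=40%
```

The control network is strongly small-world (`sigma = 3.24`); the
patient group — generated with attenuated within-cluster correlations —
shows significantly lower clustering across the whole sweep and longer
characteristic paths from 10% sparsity on, the degraded small-world
phenotype the generator injects.

`run_pipeline(run_config(...))` executes the full study end to end
(correlation matrices, small-world curves, hub tables with BrainNet
Viewer `.node`/`.edge` exports, permutation curves, white-matter ANCOVA
table, cognition correlations) and writes a JSON manifest with the MD5
checksum of every artifact; identical seeds give identical manifests.

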