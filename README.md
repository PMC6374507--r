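# connbasis

Low-rank basis sets for inter-individual variation in resting-state
functional connectomes.

## The problem

A functional connectome over a P-region parcellation has E = P(P−1)/2
edges (34,716 for 264 regions). Across people, those edges could vary
independently — or most of the differences between any two individuals
could be carried by a modest number of shared *connectivity components*.
`connbasis` implements the complete analysis pipeline for detecting,
validating and exploiting that low-rank structure, for researchers in
connectomics and network neuroscience:

- **Connectome construction** — Pearson correlation of ROI time series,
  Fisher r-to-z, a frozen edge-vectorization convention, subjects × edges
  datasets with train/test splitting.
- **Intrinsic dimensionality** — the Levina–Bickel nearest-neighbour
  maximum-likelihood estimator
  m̂ₖ(x) = [(1/(k−2)) Σⱼ log(Tₖ(x)/Tⱼ(x))]⁻¹, averaged over points and
  k = 10..20.
- **Spectral null** — a ROI-swap permutation scheme that destroys
  within-subject dependence between regions while preserving everything
  else, calibrating the PCA percent-variance spectrum.
- **Basis sets** — thin-decomposition PCA of the subjects × edges matrix;
  component expression scores; out-of-sample reconstruction curves
  (X̂ = μ + SVᵀ, equal to per-subject least squares on the components).
- **Phenotype prediction** — Brain Basis Set (BBS) regression on k
  expression scores with leakage-free fold-internal PCA cross-validation,
  a connectome predictive modelling (CPM) comparator, confound
  residualization, and Steiger's test for dependent correlations.
- **Community structure** — a Gaussian weighted stochastic block model
  profile log-likelihood ℓ = −(E/2)(log 2πσ̂² + 1) with fixed
  intrinsic-connectivity-network assignments, size-preserving
  label-permutation p-values and Bonferroni control.
- **Test-retest reliability** — ICC(2,1) per edge and per component score,
  with a permuted-component null separating genuine component alignment
  from mere edge aggregation.
- **Synthetic cohorts** — a generator that plants orthonormal
  block-structured components, a block-structured mean connectome, edge
  noise, phenotype coupling and paired retest sessions, so the entire
  pipeline runs and is validated without access-controlled imaging data.

## Worked example

```r
library(connbasis)

# 1. simulate a cohort with 5 planted components
cfg <- sim_config(
  n_subjects = 120,
  community_assignment = even_communities(30, 3),
  n_components = 5,
  eigen_spectrum = c(1.2, 1.0, 0.8, 0.7, 0.6),
  mean_connectome_scale = 0.3,
  edge_noise_sd = 0.02,
  timepoints_range = c(150, 180),
  seed = 1)
sim <- simulate_subjects(cfg)

# 2. observed Fisher-z connectomes and a train/test split
ds <- observed_dataset(sim)
sp <- split_train_test(ds, n_test = 30, seed = 2)
print(sp$train)
#> connectome_dataset: 90 subjects x 435 edges (P = 30 nodes)

# 3. intrinsic dimensionality of the latent variation
print(levina_bickel(true_z_dataset(sim)$X, k1 = 10, k2 = 20))
#> Levina-Bickel intrinsic dimensionality: 5.21 (k = 10..20, unbiased)

# 4. basis set and held-out reconstruction
bas <- fit_pca(sp$train)
rc <- reconstruction_curve(bas, sp$test, k_grid = c(1, 5, 20, 80))
print(rc$curve)
#>    k    mean_r     ci_lo     ci_hi n_missing
#> 1  1 0.8589389 0.8340817 0.8837961         0
#> 2  5 0.8944504 0.8774549 0.9114459         0
#> 3 20 0.9038705 0.8878045 0.9199364         0
#> 4 80 0.9228508 0.9092829 0.9364188         0
```

The estimator lands at 5.2 for a planted rank of 5, and five components
already recover 97% of the reconstruction ceiling achievable with all 80
(the mean edge vector shared by all subjects is responsible for the high
baseline at k = 1).

```r
# 5. phenotype prediction: BBS vs CPM on held-out subjects
phen <- simulate_phenotypes(sim, coefficients = matrix(c(1, 1, 1, 0, 0)),
                            noise_sd = 0.8, seed = 3)
y <- phen$phen1
idx_tr <- match(sp$train$subject_ids, sim$subject_ids)
idx_te <- match(sp$test$subject_ids, sim$subject_ids)
m_bbs <- fit_bbs(expression_scores(bas, sp$train, 5), y[idx_tr])
pred_bbs <- predict_bbs(m_bbs, expression_scores(bas, sp$test, 5))
m_cpm <- fit_cpm(sp$train, y[idx_tr])
pred_cpm <- predict_cpm(m_cpm, sp$test)
print(compare_methods(y[idx_te], pred_bbs, pred_cpm))
#>         r_a       r_b        diff     r_ab          z   p_value  n
#> 1 0.7904677 0.7852229 0.005244812 0.792179 0.07534425 0.9399408 30

# 6. is there community structure in the first component?
print(sbm_permutation_test(devectorize_connectome(bas$components[, 1]),
                           cfg$community_assignment, n_perm = 199, seed = 4))
#> sbm_test: loglik_obs = 1324.124, null median = 705.934, p = 0.005 (199 perms)
```

A 5-component basis predicts the phenotype as well as CPM trained on every
edge (r ≈ 0.79 for both; their difference is not significant), and the
leading component carries community structure far beyond anything label
shuffling can produce (p = 1/200, the smallest value 199 permutations
allow).

## The analysis workflow

The `analysis/` directory chains the stages into the full study on a
500-subject synthetic cohort (P = 60, 4 communities, K = 10 planted
components, series of 150–200 timepoints), writing tables under
`results/analysis/`:

```sh
Rscript analysis/01_simulate_cohort.R      # cohort, phenotypes, ground truth
Rscript analysis/02_connectomes_split.R    # observed connectomes, 400/100 split
Rscript analysis/03_dimensionality.R       # Levina-Bickel + ROI-swap null
Rscript analysis/04_basis_reconstruction.R # PCA basis + reconstruction curve
Rscript analysis/05_prediction.R           # BBS plateau, BBS vs CPM
Rscript analysis/06_network_structure.R    # SBM profile across components
Rscript analysis/07_reliability.R          # edge vs component ICC
```

`run_pipeline()` runs the same chain from a single YAML/list configuration
with a reproducibility manifest. Each stage prints what it found; on this
cohort the scripts report, among other things, a Levina–Bickel estimate of
8.4 on the latent z-truth versus 62.1 on observed connectomes (finite
series length adds near-isotropic noise), 22 spectrum components above the
ROI-swap null maximum, held-out reconstruction r = 0.78 at k = 10 (91% of
the all-component ceiling), BBS beating CPM (r = 0.64 vs 0.19) on the
component-coupled phenotype, and mean ICCs ordered edges (0.21) <
permuted components (0.42) < observed components (0.67).

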