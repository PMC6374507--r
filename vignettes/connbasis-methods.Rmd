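---
title: "Low-rank basis sets for inter-individual connectome variation: models and methods"
author: "connbasis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-rank basis sets for inter-individual connectome variation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific question

A resting-state functional connectome for a P-region parcellation has
E = P(P−1)/2 unique edges — 34,716 for a 264-node parcellation. Individuals
could in principle differ from one another along all of those edges
independently. The pipeline in this package asks whether they actually do,
or whether inter-individual variation is concentrated in a modest number of
*connectivity components*: directions in edge space, shared across the
population, whose subject-specific expression scores summarize how any one
person's connectome deviates from the population mean.

The package implements the full chain of analyses needed to answer that
question and to use the answer: connectome construction, intrinsic
dimensionality estimation, a permutation null for the eigenvalue spectrum,
PCA basis learning with out-of-sample reconstruction, phenotype prediction
from component scores, a stochastic-block-model test for network community
structure inside components, and test-retest reliability of component
scores. Because the imaging datasets such analyses are usually run on are
access-controlled, the package ships a synthetic-data generator that plants
exactly the structure the analyses assume, so every stage is exercised and
validated end to end on data with known ground truth.

# The generative model behind the synthetic cohorts

`simulate_subjects()` draws, for subject *i* with scores
*s*~ik~ ~ N(0, λ~k~²):

  z_i = M + Σ_k s_ik C_k + ε_i,     ε_i ~ N(0, σ_edge² I_E)

where the C~k~ are K orthonormal edge-space loadings built from one base
value per community-pair block plus edge-level jitter
(`make_block_components()`, Gram–Schmidt orthonormalized), M is a fixed
block-structured mean connectome, and λ is the planted score spectrum.
Correlation matrices are r~i~ = tanh(z~i~) — the inverse of the pipeline's
Fisher transform, so that connectome reconstruction targets the planted z
exactly in the noiseless limit — repaired to the PSD cone by eigenvalue
clipping with a diagonal rescale (`nearest_psd_correlation()`, floor 1e-6:
deterministic and structure-preserving). ROI time series are T~i~ i.i.d.
multivariate-normal rows with covariance r~i~, with T~i~ uniform on a
configurable range so that the spectral null's truncation step is
exercised, as with real scan lengths after motion scrubbing.

Default study conditions used by the analysis scripts and the acceptance
harness: P = 60 nodes in 4 equal communities, K = 10 components with score
standard deviations 1.5·0.9^(k−1) (a strong but decaying spectrum), mean
scale 0.3, edge noise at 10% of the per-edge component scale
(σ_edge = 0.1·sqrt(Σλ²/E)), T ∈ [150, 200], N = 400 subjects per cohort.
These sizes keep every stage within minutes on one core while leaving all
the qualitative contrasts (signal vs null separation, plateau shapes,
ICC ordering) intact.

What the generator deliberately does **not** emulate: hemodynamic
autocorrelation, motion artifacts, non-Gaussian edge distributions,
site/batch effects, family structure, or any spatial embedding of nodes.
Passing tests therefore demonstrate that the *statistical machinery* is
correct and calibrated under the model's assumptions — not that real
connectomes satisfy those assumptions.

Phenotypes are linear in the scores, y = Sb + noise
(`simulate_phenotypes()`), confounds are independent of scores unless a
coupling is requested, and retest sessions share the subject's latent
connectome. Retest has two modes: `"timeseries"` (session 2 resamples
series from r~i~; within-subject variance is the natural finite-T sampling
noise) and `"z_noise"` (sessions are z~i~ plus i.i.d. session noise, which
plants an exact between/within variance ratio — used to verify the
variance-components identity ICC = σ_b²/(σ_b² + σ_w²) at a chosen ratio).

# Connectomes and the edge convention

Edges are the upper triangle of the symmetric Fisher-z matrix in row-major
order, (i, j) with i < j, 0-based — frozen once in `edge_index()` and used
by every writer, reader and basis bundle. The matrix diagonal is defined as
0 and excluded everywhere (atanh(1) is infinite). Correlations with
|r| ≥ 1 off the diagonal are an error by default; an opt-in clip mode
(to ±(1−1e-7), with a warning) exists because degenerate synthetic
configurations should surface loudly rather than silently produce
infinities.

# Intrinsic dimensionality

`levina_bickel()` implements the nearest-neighbour maximum-likelihood
estimator: for each point and each neighbour count k in k1..k2,

  m̂_k(x) = [ (1/(k−2)) Σ_{j=1..k−1} log( T_k(x) / T_j(x) ) ]⁻¹

with T~j~ the j-th nearest-neighbour Euclidean distance; estimates are
averaged over points, then over k = 10..20 (the range recommended by the
estimator's authors). The 1/(k−2) normalization is the asymptotically
unbiased variant; `normalization = "mle"` switches to 1/(k−1). Distance
ties break by index; exact duplicate rows are an error unless a tiny jitter
(1e-9 of the data sd) is enabled. Estimates are invariant to rotation and
global rescaling, which the tests assert.

On the latent z-cohort under the default conditions the estimate lands near
8–9 for planted rank 10 — the estimator's known mild negative bias on
linear Gaussian manifolds at this sample size. On *observed* connectomes
the estimate is much larger, because finite-length series add
near-isotropic sampling noise in all E directions; the analysis scripts
show both numbers side by side, which is the right way to read such
estimates on real data too.

# The ROI-swap spectral null

To ask whether the leading PCA eigenvalues could be large by chance,
`roi_swap_null()` destroys within-subject dependence between ROIs while
keeping everything else: all series are truncated to the common minimum
length by seeded random row retention (order preserved), then each node
column independently receives a uniformly random permutation of subjects —
every subject's node-j series is used exactly once. A plain permutation is
used rather than pairwise swaps with random donors (which would need a
collision rule) and a derangement is *not* enforced; a subject may
occasionally keep its own series for some node, which only makes the null
conservative. Shuffled cohorts are rebuilt into connectomes with the same
code path as the observed data and PCA uses the same engine as the basis
module, so observed and null spectra are exactly comparable.

# The PCA basis and reconstruction

`fit_pca()` uses the thin Gram-matrix route (eigendecompose the N×N matrix
X_c X_cᵀ, recover loadings as X_cᵀU/√λ): with E ≫ N the E×E covariance is
never formed. Eigenvalues are variances and sum to the total variance of
the centered data; eigenvector sign is fixed so each column's
largest-magnitude loading is positive; components with Gram eigenvalues
below max·1e-12 are dropped as numerically null (an exactly rank-r dataset
keeps r components).

Out-of-sample operations center by the **training** mean, never the test
mean. Reconstruction is X̂ = μ + S Vᵀ. With orthonormal V this is the
least-squares fit of the training-mean-centered edge vector on the k
components; the training mean plays the role of the intercept. A freely
re-estimated per-subject intercept would differ by the projection of the
residual's edge-mean onto the constant vector — negligible scientifically
but not numerically zero, so the package's regression oracle (tested to
1e-8) is pinned to the centered, no-free-intercept form, and the k = 0
reconstruction is defined as the training mean itself. Reconstruction
quality is the Pearson correlation across edges between actual and
reconstructed *raw* vectors, so the shared mean edge vector contributes
and inflates the baseline at small k — documented because it makes small-k
correlations look better than the basis deserves.

# Phenotype prediction: BBS and CPM

Brain Basis Set modelling regresses the phenotype on k expression scores
(OLS with intercept — evaluation by correlation is intercept-invariant, but
absolute predictions should be unbiased; set `intercept = FALSE` for the
pure dot-product form). Plateau curves come from seeded k-fold
cross-validation in which **PCA is re-learned inside every fold** on the
fold-training subjects only; the held-out fold's phenotypes can influence
nothing about its own predictions, which the tests assert by perturbing
them. Per-fold correlations are averaged (not pooled), with a fold-spread
CI. Under the default conditions a phenotype carried by the first five
components gives CV correlations above 0.99 once k ≥ 5 and visibly lower
at k = 1, and a phenotype with signal fraction ½ reaches held-out
correlation ≈ √0.5.

The CPM comparator selects edges by per-edge Pearson correlation with the
phenotype using two-sided exact-t p-values below the threshold (default
0.01), sign-split into positive/negative tails (positive by default), sums
the masked edges per subject and fits a one-predictor line. An empty mask
yields a flagged degenerate model that predicts the training mean — a
contract, not a crash. One honest caveat the synthetic experiments make
visible: under strong global components, single edges are not separately
identifiable (their marginal correlations are dominated by shared
variance), so edge-recovery behaviour is validated on the generator's
unstructured mode, where edges carry independent variation.

Method comparison uses Steiger's z for two dependent correlations sharing
the criterion variable; the literature this pipeline follows bolds
significance without naming a test, and Steiger's method is the standard
choice for exactly this design. Confound removal is OLS residualization
against the confound matrix plus intercept, with residuals orthogonal to
every confound column by construction.

# Community structure: a Gaussian weighted SBM

For fixed node-community assignments z, each unordered community pair
(a, b) gets a Gaussian mean μ_ab (the mean weight of edges in that block)
and one pooled residual variance σ² across all E edges; the profile
log-likelihood at the MLE is ℓ = −(E/2)(log 2πσ̂² + 1). The pooled-variance
form makes ℓ a monotone function of within-block variance explained, which
matches how the statistic is used; a per-block-variance variant sits behind
`variance = "per_block"` and results should state which was used. σ² is
floored at 1e-12 so perfectly block-constant inputs yield a finite, flagged
value. Empty blocks (possible under permutation with small communities)
contribute nothing.

Significance comes from uniformly permuting node labels with community
sizes fixed, with the add-one p-value p = (1 + #{ℓ_null ≥ ℓ_obs})/(n_perm+1)
— valid at finite samples and never zero. Two practical consequences the
analysis scripts illustrate: the smallest achievable p is 1/(n_perm + 1),
so Bonferroni control over K components requires n_perm + 1 > K/α (199
permutations can never flag anything at K = 50, 1999 can); and on P ≤ 6
graphs the permutation p converges to the exact enumeration p over all
size-preserving assignments, which the tests verify. Type-I error is
calibrated (rejection rate ≈ α on i.i.d.-edge graphs) and power against
planted block components is essentially 1.

# Test-retest reliability

`icc_2_1()` is the single-measure absolute-agreement intraclass correlation
from the two-way random-effects ANOVA decomposition,
ICC(2,1) = (BMS − EMS)/(BMS + (k−1)EMS + k(JMS − EMS)/n), verified against
an independent `aov()` oracle to 1e-10. Zero-variance tables return NA with
a degeneracy attribute and are excluded from means (and counted) in
reports.

Component reliability uses expression scores from a basis trained on data
excluding the retest subjects (enforced, not assumed). The
permuted-component null shuffles each component's E loadings across edge
positions — preserving the loading distribution while destroying its
alignment with real structure — and summarizes each permutation by the mean
ICC over the k components; the report gives the mean and the [2.5, 97.5]
percentile interval of those per-permutation means. The interval is
interpreted as a distribution-of-means summary (its width shrinks with
n_perm), which is the reading consistent with the very narrow intervals
such analyses report. The expected ordering, which both the tests and the
analysis scripts reproduce, is: single edges < permuted components
(aggregation alone) < observed components (aggregation plus alignment with
real inter-individual structure).

# Numerical and design choices in one place

- Edge order: row-major upper triangle, i < j, 0-based; frozen everywhere.
- |r| ≥ 1: hard error by default, opt-in clipping with a warning.
- PSD repair: eigenvalue clipping at 1e-6 plus diagonal rescale.
- Levina–Bickel: (k−2) normalization default, k = 10..20, jitter opt-in,
  ties by index.
- ROI swap: per-node uniform subject permutation, no derangement
  enforcement; truncation by seeded order-preserving row retention.
- PCA: Gram route, sign fixed by largest loading, rank tolerance
  max(λ)·1e-12; training-mean centering for all out-of-sample projection.
- BBS: intercept on by default; folds are plain random partitions (real
  family structure is out of scope for synthetic cohorts).
- CPM: two-sided exact-t edge p-values, then sign split; degenerate-mask
  contract returns the training mean.
- SBM: pooled variance default, add-one p-value, variance floor 1e-12.
- ICC: ICC(2,1) only (other variants are out of scope); permutation null
  summarized by per-permutation means.
- Seeds: every stochastic function takes an explicit seed; identical
  configuration and seed reproduce outputs bitwise at the level of stored
  text.

# Known limitations

- The generator's Gaussianity (in z-space and in time) is an idealization;
  heavy-tailed edge noise would affect the CPM t-based selection and the
  SBM Gaussian likelihood first.
- The Levina–Bickel estimate on observed (finite-T) connectomes reflects
  signal plus sampling noise; only on latent or very-long-series data does
  it recover the planted rank.
- The permutation-based SBM test inherits the granularity of its p-values;
  multiple-testing control at large K needs proportionally many
  permutations.
- Community *detection* is out of scope: assignments are always fixed
  inputs.
- No rotation of the PCA basis is offered; the basis spans a subspace and
  is not unique, and rotations are deliberately left out.
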