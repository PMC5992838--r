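---
title: "Patient similarity networks and topological outcome prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient similarity networks and topological outcome prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Overview

`psntopo` classifies patients by the *position they occupy in a similarity
network* rather than by their molecular measurements directly. The pipeline
is:

1. **Preprocess** patient-by-feature omics matrices: drop features with any
   missing value, then optionally reduce dimension (Wilcoxon selection,
   variance selection, or PCA pseudo-features).
2. **Infer a Patient Similarity Network (PSN)** per data source: Pearson
   correlations between patient profiles, min-max normalized and raised to a
   soft-threshold power `beta` chosen to approximate scale-free topology.
   Multiple sources can be fused into one network with Similarity Network
   Fusion (SNF).
3. **Extract node-topological features** in four families: twelve centrality
   metrics, module-membership indicators, biased-random-walk (node2vec)
   embeddings, and diffusion signatures.
4. **Model** binary clinical endpoints with LDA, random forest or SVM,
   estimate performance by repeated stratified cross-validation, and
   integrate models with a weighted vote.

A synthetic-cohort generator with planted class signal defines the study
conditions under which every stage is validated.

## The synthetic cohort

`generate_cohort()` draws endpoint labels as independent Bernoulli variables
at the requested prevalence. For each (source, endpoint) pair,
`n_signal_features` features form a *signal block*: each is
`x = noise_sd * (sqrt(rho) * z + sqrt(1 - rho) * eps) + effect_size * noise_sd * y`,
where `z` is a per-patient latent factor shared across the block, `eps` is
independent noise and `y` the 0/1 label. This latent-factor construction
gives an exact expected pairwise correlation `rho` within the block
(conditional on class), and a mean shift of `effect_size` standard
deviations between classes. All remaining features are pure noise.
Endpoints are independent of each other by design, which keeps power
analyses interpretable. The last source can be restricted to a sub-cohort
(`small_cohort_fraction`), either a uniform random subset (default) or one
biased toward positive patients (`bias_small_to_positive`), emulating an
assay run preferentially on unusual disease courses.

`generate_modular_cohort()` plants structure in *patients* instead: members
of the same block share a latent feature profile, so same-block profile
correlation is `rho` and cross-block correlation is 0. This is the standard
input for validating soft-threshold selection and community detection.

What the generator deliberately does **not** emulate: copy-number segment
structure, platform/batch effects, heavy-tailed expression distributions,
and correlated endpoints. Tests passing on these cohorts therefore
demonstrate algorithmic correctness and sensible statistical behaviour, not
performance on real assay data.

## Network inference

For patients `a, b` with correlation `c_ab` and `C` the set of all
off-diagonal correlations, the edge weight is

    w_ab = ((c_ab - min(C)) / (max(C) - min(C)))^beta.

Negative correlations are handled implicitly by the min-max shift — no
absolute value is taken, matching the formula as printed above. The network
is complete (no pruning); one pair always lands exactly at weight 0 (the
minimum correlation) and one at weight 1.

`beta` is chosen as the smallest candidate in `{2, 4, 6, 8, 10, 12}` whose
*truncated scale-free fit index* reaches 0.90; `beta = 1` (plain min-max
normalization) is kept as a control network. The fit index bins the
weighted degrees `k_i = sum_j w_ij` into 10 equal-width bins (empty bins
dropped; for networks under 30 nodes the bin count shrinks to about n/3)
and returns the R-squared of regressing `log10(frequency)` on `log10(mean k)`
and `mean k` jointly — a truncated exponential power law. Two numerical
caveats are documented deliberately: (i) the regression R-squared is
reported unsigned, and (ii) over the narrow connectivity range of a dense
network `log10(k)` and `k` are nearly collinear, so the two-term model can
also fit bell-shaped degree histograms well. The index is therefore used as
the *selection criterion the method prescribes*, not as a general test for
scale-freeness. If no candidate reaches the target, the best-fitting
candidate is returned with a structured warning
(`psntopo_no_scale_free_beta`) — never silently.

**SNF fusion.** Fusion operates directly on the rescaled similarity
matrices (the same networks used everywhere else). Each network becomes a
row-normalized full kernel `P` (off-diagonal mass 1/2, diagonal 1/2) and a
K-nearest-neighbour local kernel `S`; the update
`P_v <- S_v %*% mean(P_u, u != v) %*% t(S_v)` runs for `T` rounds
(defaults `K = 10`, `T = 50`), with symmetrization and renormalization each
round. The output is the symmetrized average, min-max rescaled to [0, 1].

## Topological features

**Centrality (12 columns, fixed order).** Weighted degree; closeness and
load use shortest paths with distance `1/w` (zero-weight pairs are treated
as absent edges — the common weighted-graph convention; `1 - w` is the
documented alternative); current-flow closeness and betweenness treat
weights as electrical conductances, computed from the Laplacian
pseudoinverse; eigenvector, Katz (attenuation `0.9 / lambda_max`), HITS
(hub and authority coincide on an undirected graph; the authority vector is
used) and PageRank (damping 0.85) treat weights as affinities; the local
clustering coefficient uses the Onnela geometric-mean definition
(max-normalized weights), chosen because the weighted variant is otherwise
underdetermined. The two *iterative* variants repeatedly record the most
central node's value, remove that node, and recompute on the shrinking
network; ties break by ascending patient id and the final singleton records
degree 0. All centralities are standardized column-wise to zero mean and
unit population SD (the `1/n` denominator, so a standardized column has
exactly unit mean square); zero-variance columns become all-zeros with a
warning.

**Modularity.** Two clustering families partition each network:
normalized-Laplacian spectral clustering with the module count chosen by
eigengap, and a Poisson degree-corrected stochastic block model fit by
greedy move sweeps from a spectral initialization, selected by a
description-length style criterion `-logLik + (k(k+1)/2) log(n_pairs)` with
a single-block null always evaluated (so uniform networks prefer one
block). Because several module counts are often near-optimal, every `k`
within 5% of the best criterion is retained, and each retained partition is
one-hot encoded; the feature block has `sum(k_s)` binary columns. Module
labels are canonicalized by size for reproducibility. The choice of
eigengap and description length stands in for unnamed package-specific
selection rules and is switchable through `k_range`/`tolerance`.

**Embedding.** Second-order biased random walks (return parameter `p`,
in-out parameter `q`): the unnormalized step weight to node `x` is
`w(cur, x) / p` when `x` is the previous node, `w(cur, x)` when `x`
neighbours the previous node, and `w(cur, x) / q` otherwise. Defaults
follow the node2vec conventions: 10 walks of length 80 per node, window 10,
`d = 128`. Two runs — `(p, q) = (1, 4)` (local) and `(4, 1)` (exploratory)
— are concatenated into 256 features. Training is skip-gram with negative
sampling (5 negatives, 5 epochs, linearly decayed learning rate),
single-threaded with a deterministic internal RNG so the same seed gives
bit-identical embeddings. Because PSNs are dense, transition weights are
sampled on the fly per step instead of via precomputed alias tables: for a
complete graph the alias tables would cost O(n^2) memory and O(n^3) setup
while per-step cumulative sampling is O(n), which is cheaper at every
realistic cohort size.

**Diffusion.** The default kernel is the regularized Laplacian
`K = (I + L)^(-1)` (always invertible, symmetric PSD), with the heat kernel
`exp(-tL)` as an alternative; the kernel is computed once and reused. Each
of the 1,000 diffusion rounds seeds a random 10% of the nodes with signal 1
(the rest 0) and stores the full post-diffusion signal `K y` as one feature
column. Seed sets are drawn without replacement and recorded for exact
replay. The seed count is `round(0.1 * n)` and must be at least 1 — a
cohort too small to seed a single node is rejected as invalid input.

## Classification

Splits are stratified per class with a `ceiling(fraction * n_class)` rule,
so train/test class proportions agree within one patient. Performance is
estimated by ten-times five-fold stratified cross-validation (50 fits) on
the training split only. Classifiers: LDA (falling back to a
ridge-shrinkage pooled-covariance discriminant when the within-class
covariance is singular, e.g. p >= n), random forest (500 trees, default
subsampling), and SVM (radial or linear; when optimized, cost and width are
scanned over `2^(2p)` for `p` in `{-4, -2, -1, 0, 1, 2, 4}` by internal
cross-validation on the training set, ties going to the first candidate in
scan order). Feature scaling is always computed on training rows only.
Reported metrics are ACC, balanced accuracy (bACC) and Matthews correlation
(MCC, defined as 0 when a confusion marginal is empty).

Topological features are *transductive*: the PSN is built over training and
test patients together, but labels never enter network construction or
feature extraction — only model fitting sees them. This is the intended
design of PSN-based classification and is stated explicitly so users do not
mistake the test estimates for fully inductive ones.

**Weighted voting.** Member models are combined with weights proportional
to their cross-validated mean bACC (the only leakage-free performance
estimate available before touching the test split), normalized to sum to
one; the consensus score is thresholded at 0.5, with the exact tie called
positive (deterministic rule). **Comparisons** between model groups use
Welch t-tests (two groups) or one-way ANOVA with post-hoc Tukey HSD (more),
significance at p < 0.01, and always report the accuracy gain
`delta_bACC = mean(A) - mean(B)` alongside p-values.

For the Wilcoxon reduction, the rank-sum test is exact when both classes
have at most 10 patients (and no ties) and uses the tie-corrected normal
approximation otherwise; fully tied features get p = 1. Selection
statistics are computed on training patients only by default
(`fit_scope = "train_only"`); an `all_samples` mode exists because either
reading of the upstream protocol is defensible, and the package does not
guess intent.

## Determinism

Every stochastic stage draws its seed from the master seed through a stable
string hash (`derive_seed(master, stage, ...)`), so no two stages share a
stream and a rerun with the same configuration reproduces the output tree
bit-for-bit (this is asserted by hashing all run artifacts in the test
suite). Random forest, k-means, SVM probability calibration and base-R
sampling are all reseeded per call; the walk/embedding code uses its own
deterministic xorshift RNG, making corpora identical across platforms.

## Problem sizes used in the validation suite

The test suite and acceptance script run entirely on synthetic cohorts:
beta selection and parameter recovery use 200 patients x 500 features
(4 blocks at rho = 0.7 for the modular design; 50 signal features at
effect size 2 SD for the labelled design); community-detection and fusion
checks use 20-60 node networks; embedding and diffusion contracts are
asserted at the full d = 128 / 1,000-column widths. These sizes were chosen
so that planted structure is comfortably detectable (power near 1) while a
full validation run remains a desk-scale computation.

## Known limitations

- The scale-free fit index inherits the collinearity caveat above; it
  ranks soft-threshold candidates well but should not be read as a
  hypothesis test.
- SBM fitting is a greedy maximum-profile-likelihood heuristic; on weak
  contrasts it can return locally optimal partitions (the spectral
  initialization makes this rare on block-structured PSNs).
- Classification on fused networks restricts to the patients covered by
  every source; cross-cohort comparisons (large vs small) therefore differ
  in sample size and should be interpreted with that in mind.
- All validation evidence is synthetic; real multi-omics cohorts bring
  batch structure, missingness patterns and label noise the generator does
  not model.
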