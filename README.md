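# psntopo

Network-based outcome prediction for multi-omics patient cohorts.

Large cohorts are routinely profiled with several high-throughput assays at
once (microarray and RNA-seq expression, array CGH, ...). `psntopo`
implements an integrative strategy for predicting **binary clinical
endpoints** from such data that never feeds the molecular measurements to a
classifier directly. Instead it:

1. builds a **Patient Similarity Network (PSN)** per data source — a
   complete weighted graph whose nodes are patients and whose edge weights
   are soft-thresholded Pearson correlations between molecular profiles,

   `w_ab = ((c_ab − min(C)) / (max(C) − min(C)))^β`,

   with β the smallest power in {2, 4, 6, 8, 10, 12} whose truncated
   scale-free fit index reaches 90% (β = 1 kept as a "correl" control), and
   optionally fuses several sources with Similarity Network Fusion
   (K = 10 neighbours, T = 50 iterations);
2. represents every patient by **node-topological features** in four
   families: twelve centrality metrics (including iterative
   remove-the-most-central variants), one-hot module memberships from
   spectral and stochastic-block-model clustering, 256 node2vec embedding
   dimensions from two biased-random-walk runs ((p, q) = (1, 4) and
   (4, 1), d = 128), and 1,000 diffusion features (random 10% seed sets
   propagated through a regularized-Laplacian kernel);
3. trains **LDA / random forest / SVM** models per feature family and
   endpoint, estimates performance with ten-times five-fold stratified
   cross-validation (ACC, balanced accuracy, Matthews correlation), and
   integrates models by **weighted voting** (weights proportional to CV
   performance, consensus thresholded at 0.5).

A synthetic-cohort generator with planted, tunable class signal makes the
whole pipeline testable without any external data; it is first-class,
tested code, not a fixture. The package is aimed at methodologists studying
network-based patient classification and at analysts who want a
reproducible, seed-deterministic reference implementation of the PSN →
topology → classification workflow.

## Worked example

```r
library(psntopo)

# 1. simulate a cohort: 120 patients, one expression source, one endpoint
spec <- cohort_spec(n_patients = 120, sources = c(expr = 300),
                    endpoints = c(relapse = 0.4),
                    n_signal_features = 40, effect_size = 1.5,
                    block_correlation = 0.3, rng_seed = 7)
cohort <- generate_cohort(spec)
labels <- setNames(cohort$clinical[, "relapse"], rownames(cohort$clinical))

# 2. reduce features and infer the patient similarity network
expr <- wilcoxon_select(cohort$omics$expr, labels, "significant")
sel <- select_beta(pearson_psn(expr))
sel$psn
#> patient similarity network: 120 patients, tag=WGCNA, beta=4, fit=0.9448945

# 3. extract topological features (three families shown)
feats <- topological_features(sel$psn,
                              families = c("centrality", "modularity", "diffusion"),
                              n_diffusions = 1000, rng_seed = 7)
sapply(feats, ncol)
#> centrality modularity  diffusion
#>         12          7       1000

# 4. one SVM per family, then weighted-vote integration
split <- stratified_split(labels, 0.5, rng_seed = 7)
models <- lapply(names(feats), function(fam) {
  cv <- crossvalidate(feats[[fam]][split$train, ], labels[split$train],
                      "svm", rng_seed = 7)
  fit <- train_predict(feats[[fam]], labels, split, "svm", rng_seed = 7)
  list(fam = fam, cv = cv$cv_mean_bACC, fit = fit)
})
for (m in models) { cat(sprintf("%-11s cv bACC = %.3f  test: ", m$fam, m$cv)); print(m$fit$report) }
#> centrality  cv bACC = 0.914  test: ACC=0.9322 bACC=0.9298 MCC=0.8595 (TP=22 FP=2 FN=2 TN=33)
#> modularity  cv bACC = 0.918  test: ACC=0.9153 bACC=0.9220 MCC=0.8322 (TP=23 FP=4 FN=1 TN=31)
#> diffusion   cv bACC = 0.911  test: ACC=0.8983 bACC=0.8881 MCC=0.7885 (TP=20 FP=2 FN=4 TN=33)

vote <- weighted_vote(lapply(models, function(m) m$fit$scores),
                      vapply(models, function(m) m$cv, numeric(1)))
compute_metrics(labels[split$test], vote$predictions)
#> ACC=0.9153 bACC=0.9220 MCC=0.8322 (TP=23 FP=4 FN=1 TN=31)
```

The soft threshold lands at β = 4 (scale-free fit 0.945); each feature
family alone predicts the planted endpoint at balanced accuracy ≈ 0.89–0.93
on the held-out half, and the vote (weights 0.333/0.335/0.332, proportional
to the cross-validated bACC of the members) matches the best members. On a
label-permuted control the same pipeline collapses to chance — see
`tests/testthat/test-acceptance.R`.

`run_pipeline()` orchestrates the same flow end to end from a YAML config
(modes `classical`, `topological`, `integrated`, `fused`), writing
networks, feature TSVs, per-model reports, vote consensus and comparison
tables under an output directory, bit-reproducibly from one master seed.
A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/psntopo.R simulate --seed 7 --out cohort/
Rscript inst/cli/psntopo.R infer --omics cohort/expr.tsv --out net.tsv
Rscript inst/cli/psntopo.R features --network net.tsv --family centrality --out cent.tsv
Rscript inst/cli/psntopo.R run --config config.yaml
```

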