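# fixtures built in code: planted-block PSNs and small weight matrices

make_ids <- function(n) sprintf("P%03d", seq_len(n))

# symmetric weight matrix -> psn, filling dimnames
psn_from_matrix <- function(w, tag = "WGCNA", beta = 2) {
  ids <- make_ids(nrow(w))
  dimnames(w) <- list(ids, ids)
  new_psn((w + t(w)) / 2, tag = tag, beta = beta)
}

# complete PSN with planted patient blocks: high within-block weight, low
# between, small uniform jitter
make_block_psn <- function(n, k, within = 0.9, between = 0.1, noise = 0.02,
                           seed = 1) {
  set.seed(seed)
  b <- rep(seq_len(k), length.out = n)
  w <- matrix(between, n, n) + noise * matrix(runif(n * n), n, n)
  same <- outer(b, b, "==")
  w[same] <- within + noise * runif(sum(same))
  w <- (w + t(w)) / 2
  w[w > 1] <- 1
  diag(w) <- 0
  list(psn = psn_from_matrix(w), block = b)
}

# equal-weight complete graph
make_complete_psn <- function(n, w = 0.5) {
  m <- matrix(w, n, n)
  diag(m) <- 0
  psn_from_matrix(m)
}

# quick single-source cohort with planted signal
make_signal_cohort <- function(n = 200, f = 500, n_signal = 50, effect = 2,
                               prevalence = 0.5, seed = 101) {
  generate_cohort(cohort_spec(
    n_patients = n, sources = c(expr = f), endpoints = c(outcome = prevalence),
    n_signal_features = n_signal, effect_size = effect,
    block_correlation = 0.3, rng_seed = seed))
}

labels_of <- function(cohort, endpoint = 1) {
  setNames(cohort$clinical[, endpoint], rownames(cohort$clinical))
}
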