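test_that("patient-patient Pearson correlations match hand computation", {
  m <- rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 2, 1))
  colnames(m) <- paste0("f", 1:3)
  cm <- pearson_psn(m)
  expect_equal(cm["a", "b"], 1)
  expect_equal(cm["a", "c"], -1)
  expect_equal(cm["b", "c"], -1)
  expect_equal(diag(cm), c(a = 1, b = 1, c = 1))
  # zero-variance profile is rejected with the patient named
  m2 <- rbind(m, d = c(5, 5, 5))
  expect_error(pearson_psn(m2), "d")
})

test_that("soft thresholding follows the min-max power formula", {
  ids <- make_ids(4)
  cm <- diag(4)
  cm[1, 2] <- cm[2, 1] <- 0.2   # min(C)
  cm[3, 4] <- cm[4, 3] <- 0.8   # max(C)
  cm[1, 3] <- cm[3, 1] <- 0.5
  cm[1, 4] <- cm[4, 1] <- 0.4
  cm[2, 3] <- cm[3, 2] <- 0.6
  cm[2, 4] <- cm[4, 2] <- 0.35
  dimnames(cm) <- list(ids, ids)
  for (beta in c(1, 2, 6)) {
    psn <- rescale_correlations(cm, beta)
    expect_equal(psn$w[1, 2], 0)            # c = min(C) -> 0 for any beta
    expect_equal(psn$w[3, 4], 1)            # c = max(C) -> 1 for any beta
    expect_equal(diag(psn$w), setNames(rep(0, 4), ids))
  }
  expect_equal(rescale_correlations(cm, 2)$w[1, 3], 0.25)  # ((0.5-0.2)/0.6)^2
  expect_identical(rescale_correlations(cm, 1)$meta$tag, "correl")
  expect_identical(rescale_correlations(cm, 2)$meta$tag, "WGCNA")
  # beta = 1 is plain min-max normalization
  w1 <- rescale_correlations(cm, 1)$w
  expect_equal(w1[1, 3], (0.5 - 0.2) / 0.6)
})

test_that("soft thresholding is monotone in the correlation", {
  set.seed(10)
  x <- matrix(rnorm(20 * 50), 20, 50,
              dimnames = list(make_ids(20), sprintf("f%02d", 1:50)))
  cm <- pearson_psn(x)
  for (beta in c(1, 2, 8)) {
    w <- rescale_correlations(cm, beta)$w
    up <- upper.tri(cm)
    ord <- order(cm[up])
    expect_true(all(diff(w[up][ord]) >= -1e-12))
  }
})

test_that("degenerate correlation ranges are rejected", {
  cm <- matrix(0.5, 3, 3)
  diag(cm) <- 1
  dimnames(cm) <- list(make_ids(3), make_ids(3))
  expect_error(rescale_correlations(cm, 2), "degenerate")
})

test_that("connectivities generated on the fitted model give R^2 = 1", {
  # pure power law p(k) ~ k^-1 on 10 equal-width-separated support points;
  # counts L / i with L = lcm(1..10) are exact, so the regression (which
  # also carries the exponential-truncation term) has zero residuals
  L <- 2520
  k <- unlist(lapply(1:10, function(i) rep(100 * i, L / i)))
  # suppress the perfect-fit note from summary.lm; the value is the check
  expect_equal(suppressWarnings(scale_free_fit_index(k, bins = 10)), 1,
               tolerance = 1e-9)
})

test_that("the fit index is bounded and degenerate connectivity warns", {
  set.seed(11)
  for (s in 1:5) {
    k <- runif(120, 1, 50)
    fit <- scale_free_fit_index(k)
    expect_gte(fit, 0)
    expect_lte(fit, 1)
  }
  expect_warning(val <- scale_free_fit_index(rep(3, 50)), "equal")
  expect_equal(val, 0)
})

test_that("beta selection matches a brute-force scan of all candidates", {
  cands <- c(2, 4, 6, 8, 10, 12)
  for (s in c(2, 3, 8)) {
    m <- generate_modular_cohort(200, 500, n_blocks = 4, rho = 0.7, rng_seed = s)
    cm <- pearson_psn(m)
    fits <- vapply(cands, function(b)
      scale_free_fit(rescale_correlations(cm, b)), numeric(1))
    sel <- suppressWarnings(select_beta(cm, cands))
    qualified <- cands[fits >= 0.90]
    oracle <- if (length(qualified)) min(qualified) else cands[which.max(fits)]
    expect_equal(sel$beta, oracle)
    expect_equal(sel$fit_index, fits[cands == oracle], tolerance = 1e-12)
    expect_equal(sel$psn$meta$beta, oracle)
  }
})

test_that("beta selection returns the smallest qualifying power, not the best", {
  m <- generate_modular_cohort(200, 500, n_blocks = 4, rho = 0.7, rng_seed = 8)
  cm <- pearson_psn(m)
  fits <- vapply(c(2, 4, 6, 8, 10, 12), function(b)
    scale_free_fit(rescale_correlations(cm, b)), numeric(1))
  # this cohort has a later beta fitting better than the first qualifier
  expect_true(fits[1] >= 0.90 && any(fits[-1] > fits[1]))
  expect_equal(select_beta(cm)$beta, 2)
})

test_that("a zero target returns the first candidate; failure warns structurally", {
  m <- generate_modular_cohort(120, 200, n_blocks = 4, rho = 0.7, rng_seed = 2)
  cm <- pearson_psn(m)
  expect_equal(select_beta(cm, scale_free_target = 0)$beta, 2)
  expect_warning(sel <- select_beta(cm, scale_free_target = 0.999999),
                 class = "psntopo_no_scale_free_beta")
  expect_true(sel$beta %in% c(2, 4, 6, 8, 10, 12))
  expect_equal(nrow(sel$scan), 6)
  expect_equal(sel$fit_index, max(sel$scan$fit))
})

test_that("self-fusion preserves each node's K-nearest-neighbour set", {
  # 4 blocks of exactly K + 1 nodes: the KNN set of every node is its block
  set.seed(4)
  n <- 44
  K <- 10
  b <- rep(1:4, each = 11)
  w <- matrix(0.1, n, n) + 0.02 * matrix(runif(n * n), n, n)
  w <- (w + t(w)) / 2
  same <- outer(b, b, "==")
  w[same] <- 0.85 + 0.05 * runif(sum(same))
  w <- (w + t(w)) / 2
  w[w > 1] <- 1
  diag(w) <- 0
  psn <- psn_from_matrix(w)
  fused <- fuse_networks(list(psn, psn), K = K, T = 20)
  knn <- function(m) lapply(seq_len(nrow(m)), function(i) {
    wi <- m[i, ]
    wi[i] <- -Inf
    sort(order(wi, decreasing = TRUE)[seq_len(K)])
  })
  expect_true(all(mapply(identical, knn(psn$w), knn(fused$w))))
})

test_that("fusion converges: iterate changes shrink monotonically late on", {
  a <- make_block_psn(40, 2, seed = 5)$psn
  b <- make_block_psn(40, 2, within = 0.85, seed = 6)$psn
  fused <- fuse_networks(list(a, b), K = 8, T = 50, trace = TRUE)
  d <- attr(fused, "delta")
  expect_length(d, 50)
  expect_true(all(diff(tail(d, 10)) <= 1e-10))
})

test_that("fused networks satisfy the PSN invariants and reject mismatched ids", {
  a <- make_block_psn(30, 3, seed = 7)$psn
  b <- make_block_psn(30, 2, seed = 8)$psn
  fused <- fuse_networks(list(a, b), K = 5, T = 10)
  expect_s3_class(fused, "psn")
  expect_identical(fused$meta$tag, "fused")
  expect_equal(fused$w, t(fused$w))
  expect_true(all(fused$w >= 0 & fused$w <= 1))
  expect_equal(unname(diag(fused$w)), rep(0, 30))
  c_small <- make_block_psn(20, 2, seed = 9)$psn
  expect_error(fuse_networks(list(a, c_small)), "P021")
})

test_that("produced networks satisfy the PSN invariants under fuzzing", {
  for (s in 1:10) {
    set.seed(s)
    n <- sample(5:20, 1)
    x <- matrix(rnorm(n * 30), n, 30,
                dimnames = list(make_ids(n), sprintf("f%02d", 1:30)))
    psn <- rescale_correlations(pearson_psn(x), sample(c(1, 2, 6, 12), 1))
    expect_equal(psn$w, t(psn$w))
    expect_true(all(psn$w >= 0 & psn$w <= 1))
    expect_true(all(diag(psn$w) == 0))
    expect_false(anyNA(psn$w))
  }
})

test_that("networks round-trip through edge lists and export to GraphML", {
  psn <- make_block_psn(12, 2, seed = 3)$psn
  dir <- withr::local_tempdir()
  f <- file.path(dir, "net.tsv")
  write_psn_edgelist(psn, f)
  back <- read_psn_edgelist(f)
  expect_equal(back$w, psn$w, tolerance = 1e-12)
  expect_identical(back$meta$tag, psn$meta$tag)
  g <- file.path(dir, "net.graphml")
  write_psn_graphml(psn, g)
  expect_true(file.exists(g))
  reread <- igraph::read_graph(g, format = "graphml")
  expect_equal(igraph::gsize(reread), sum(psn$w[upper.tri(psn$w)] > 0))
})
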