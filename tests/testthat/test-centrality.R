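test_that("the feature block has exactly twelve named columns, in order", {
  psn <- make_block_psn(15, 3, seed = 1)$psn
  feats <- compute_centralities(psn)
  expect_equal(ncol(feats), 12)
  expect_identical(colnames(feats),
                   c("weighted_degree", "closeness", "current_flow_closeness",
                     "current_flow_betweenness", "eigenvector", "katz", "hits",
                     "pagerank", "load", "local_clustering",
                     "iterative_weighted_degree", "iterative_local_clustering"))
  expect_identical(attr(feats, "family"), "centrality")
  expect_false(anyNA(feats))
})

test_that("non-iterative centralities are constant on a vertex-transitive graph", {
  feats <- compute_centralities(make_complete_psn(8, 0.4))
  for (col in setdiff(colnames(feats), c("iterative_weighted_degree",
                                         "iterative_local_clustering")))
    expect_lt(diff(range(feats[, col])), 1e-8)
})

test_that("a dominant pair attains the two largest weighted degrees", {
  w <- matrix(0.01, 4, 4)
  w[1, 2] <- w[2, 1] <- 1
  diag(w) <- 0
  feats <- compute_centralities(psn_from_matrix(w))
  expect_setequal(make_ids(4)[order(-feats[, "weighted_degree"])][1:2],
                  c("P001", "P002"))
})

test_that("closeness and pagerank match independent brute-force oracles", {
  set.seed(12)
  w <- matrix(runif(25, 0.2, 1), 5, 5)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  psn <- psn_from_matrix(w)
  feats <- compute_centralities(psn)
  n <- 5
  # oracle 1: Dijkstra on distances 1/w, closeness = 1 / sum of distances
  dijkstra <- function(s) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    done <- rep(FALSE, n)
    for (it in 1:n) {
      u <- which.min(ifelse(done, Inf, dist))
      done[u] <- TRUE
      for (v in 1:n) if (w[u, v] > 0 && !done[v])
        dist[v] <- min(dist[v], dist[u] + 1 / w[u, v])
    }
    dist
  }
  clo_oracle <- vapply(1:n, function(s) 1 / sum(dijkstra(s)[-s]), numeric(1))
  expect_equal(unname(feats[, "closeness"]), clo_oracle, tolerance = 1e-8)
  # oracle 2: pagerank by explicit power iteration
  P <- w / rowSums(w)
  pr <- rep(1 / n, n)
  for (it in 1:2000) pr <- 0.15 / n + 0.85 * as.numeric(t(P) %*% pr)
  pr <- pr / sum(pr)
  expect_equal(unname(feats[, "pagerank"]), pr, tolerance = 1e-6)
})

test_that("load centrality matches the closed form on a star graph", {
  n <- 6
  w <- matrix(0, n, n)
  w[1, 2:n] <- w[2:n, 1] <- 0.7
  feats <- compute_centralities(psn_from_matrix(w))
  # every ordered spoke pair routes its packet through the hub:
  # (n-1)(n-2) packets over the (n-1)(n-2) normalizer
  expect_equal(unname(feats[1, "load"]), 1, tolerance = 1e-10)
  expect_equal(unname(feats[2:n, "load"]), rep(0, n - 1))
})

test_that("iterative removal follows the recorded-at-removal contract", {
  # path a-b-c with unit weights: b removed first at degree 2, the isolated
  # survivors both record 0
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1
  w[2, 3] <- w[3, 2] <- 1
  psn <- psn_from_matrix(w, beta = 1)
  psn$w <- w  # exact unit weights
  out <- iterative_centrality(psn, "weighted_degree")
  expect_equal(out, c(P001 = 0, P002 = 2, P003 = 0))
  # equal-weight triangle: ids break ties, values 2w, w, 0
  tri <- make_complete_psn(3, 0.5)
  expect_equal(iterative_centrality(tri, "weighted_degree"),
               c(P001 = 1.0, P002 = 0.5, P003 = 0))
  # singleton keeps its degree-0 convention
  single <- psn_from_matrix(matrix(0, 1, 1))
  expect_equal(unname(iterative_centrality(single, "weighted_degree")), 0)
})

test_that("iterative centralities equal a naive removal simulation (fuzzed)", {
  naive_degree <- function(w) sapply(seq_len(nrow(w)), function(i) sum(w[i, ]))
  naive_onnela <- function(w) {
    nn <- nrow(w)
    mx <- max(w)
    out <- numeric(nn)
    if (mx <= 0) return(out)
    for (i in seq_len(nn)) {
      nbr <- which(w[i, ] > 0)
      if (length(nbr) < 2) next
      tot <- 0
      for (j in nbr) for (l in nbr) if (j != l && w[j, l] > 0)
        tot <- tot + (w[i, j] / mx * w[j, l] / mx * w[i, l] / mx)^(1 / 3)
      out[i] <- tot / (length(nbr) * (length(nbr) - 1))
    }
    out
  }
  simulate <- function(w, ids, base_fun) {
    left <- seq_along(ids)
    res <- setNames(numeric(length(ids)), ids)
    while (length(left) > 0) {
      vals <- base_fun(w[left, left, drop = FALSE])
      top <- order(-vals, ids[left])[1]
      res[ids[left][top]] <- vals[top]
      left <- left[-top]
    }
    res
  }
  for (s in 1:8) {
    set.seed(s)
    n <- sample(3:7, 1)
    w <- matrix(runif(n * n) * rbinom(n * n, 1, 0.7), n, n)
    w <- (w + t(w)) / 2
    diag(w) <- 0
    psn <- psn_from_matrix(w)
    ids <- psn$patient_ids
    expect_equal(iterative_centrality(psn, "weighted_degree"),
                 simulate(psn$w, ids, naive_degree), tolerance = 1e-12)
    expect_equal(iterative_centrality(psn, "local_clustering"),
                 simulate(psn$w, ids, naive_onnela), tolerance = 1e-10)
  }
})

test_that("standardization is exact, warns on constants, and is idempotent", {
  m <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(0, 10, 20))
  rownames(m) <- make_ids(3)
  expect_warning(z <- standardize_features(m), "zero-variance")
  expect_equal(unname(z[, "a"]), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(unname(z[, "b"]), rep(0, 3))
  expect_equal(colMeans(z[, c("a", "c")]), c(a = 0, c = 0), tolerance = 1e-12)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  expect_equal(apply(z[, c("a", "c")], 2, pop_sd), c(a = 1, c = 1),
               tolerance = 1e-12)
  z2 <- suppressWarnings(standardize_features(z))
  expect_equal(z2, z, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("negative weights are rejected", {
  w <- matrix(0.5, 3, 3)
  w[1, 2] <- w[2, 1] <- -0.1
  diag(w) <- 0
  ids <- make_ids(3)
  dimnames(w) <- list(ids, ids)
  psn <- structure(list(w = w, patient_ids = ids,
                        meta = list(tag = "WGCNA", beta = 2,
                                    source_tag = NA, fit_index = NA)),
                   class = "psn")
  expect_error(compute_centralities(psn), "negative")
})
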