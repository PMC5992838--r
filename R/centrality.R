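# Onnela (geometric-mean) weighted local clustering coefficient.
# Weights are normalized by the network maximum; nodes with < 2 neighbours
# get 0.
.onnela_clustering <- function(w) {
  n <- nrow(w)
  k <- rowSums(w > 0)
  mx <- max(w)
  if (mx <= 0) return(setNames(numeric(n), rownames(w)))
  m3 <- (w / mx)^(1 / 3)
  num <- diag(m3 %*% m3 %*% m3)
  out <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  setNames(out, rownames(w))
}

# Inverse of (L + J/n): pairwise differences equal those of the Laplacian
# pseudoinverse, which is all the current-flow metrics need.
.laplacian_inverse <- function(w) {
  n <- nrow(w)
  L <- diag(rowSums(w)) - w
  solve(L + 1 / n)
}

.current_flow_closeness <- function(w, Phi = .laplacian_inverse(w)) {
  n <- nrow(w)
  d <- diag(Phi)
  # effective resistance R_ij = Phi_ii + Phi_jj - 2 Phi_ij; row sums thereof
  rsum <- n * d + sum(d) - 2 * rowSums(Phi)
  setNames((n - 1) / rsum, rownames(w))
}

# Current-flow betweenness: for each edge e = (u, v), the s->t current on e
# is w_e * (Phi[u, s] - Phi[v, s] - Phi[u, t] + Phi[v, t]); summing absolute
# currents over all pairs reduces, per edge, to a sorted weighted sum.
# A node's score is half the total absolute current on its incident edges,
# normalized by (n - 1) * (n - 2).
.current_flow_betweenness <- function(w, Phi = .laplacian_inverse(w)) {
  n <- nrow(w)
  e <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  B <- (Phi[e[, 1], , drop = FALSE] - Phi[e[, 2], , drop = FALSE]) * w[e]
  coefs <- 2 * seq_len(n) - n - 1
  Se <- apply(B, 1, function(b) sum(sort(b) * coefs))
  cfb <- numeric(n)
  for (kcol in 1:2) {
    agg <- rowsum(Se, e[, kcol])
    i <- as.integer(rownames(agg))
    cfb[i] <- cfb[i] + agg[, 1]
  }
  if (n > 2) cfb <- cfb / 2 / ((n - 1) * (n - 2))
  setNames(cfb, rownames(w))
}

.centrality_columns <- c("weighted_degree", "closeness", "current_flow_closeness",
                         "current_flow_betweenness", "eigenvector", "katz",
                         "hits", "pagerank", "load", "local_clustering",
                         "iterative_weighted_degree", "iterative_local_clustering")

#' Twelve node-centrality features of a PSN
#'
#' Computes the twelve centrality metrics on the weighted network:
#' weighted degree, closeness, current-flow closeness, current-flow
#' betweenness, eigenvector, Katz, HITS (hub/authority, which coincide on an
#' undirected graph), PageRank, load, the Onnela weighted local clustering
#' coefficient, and the iterative variants of weighted degree and local
#' clustering (see [iterative_centrality()]). Shortest-path metrics
#' (closeness, load) use distance `1/weight`; spectral and flow metrics use
#' the weight as affinity/conductance. Zero-weight pairs are treated as
#' absent edges; negative weights are an error. Values are raw — pass the
#' result through [standardize_features()] before modeling.
#'
#' @param psn a [new_psn()] object with at least 2 patients.
#' @return patients x 12 matrix (fixed column order), `family` attribute
#'   `"centrality"`.
#' @export
compute_centralities <- function(psn) {
  .assert(inherits(psn, "psn"), "psn must be a psn object")
  w <- psn$w
  n <- nrow(w)
  .assert(n >= 2, "need at least 2 patients")
  .assert(min(w) >= 0, "negative edge weight: cannot form distances")
  g <- psn_to_igraph(psn)
  ew <- igraph::E(g)$weight

  Phi <- .laplacian_inverse(w)
  closeness <- suppressWarnings(igraph::closeness(g, weights = 1 / ew))
  closeness[!is.finite(closeness)] <- 0
  eig <- igraph::eigen_centrality(g, weights = ew)$vector
  hits <- if ("hits_scores" %in% getNamespaceExports("igraph")) {
    igraph::hits_scores(g, weights = ew)$authority
  } else {
    suppressWarnings(igraph::authority_score(g, weights = ew)$vector)
  }
  pr <- igraph::page_rank(g, damping = 0.85, weights = ew)$vector
  lam <- max(abs(eigen(w, symmetric = TRUE, only.values = TRUE)$values))
  katz <- as.numeric(solve(diag(n) - (0.9 / lam) * w, rep(1, n)))
  katz <- katz / sqrt(sum(katz^2))

  out <- cbind(
    weighted_degree = rowSums(w),
    closeness = as.numeric(closeness),
    current_flow_closeness = .current_flow_closeness(w, Phi),
    current_flow_betweenness = .current_flow_betweenness(w, Phi),
    eigenvector = as.numeric(eig),
    katz = katz,
    hits = as.numeric(hits),
    pagerank = as.numeric(pr),
    load = as.numeric(.cpp_load_centrality(w)),
    local_clustering = .onnela_clustering(w),
    iterative_weighted_degree = iterative_centrality(psn, "weighted_degree"),
    iterative_local_clustering = iterative_centrality(psn, "local_clustering"))
  rownames(out) <- psn$patient_ids
  attr(out, "family") <- "centrality"
  attr(out, "standardized") <- FALSE
  out
}

#' Iterative centrality by most-central-node removal
#'
#' Repeatedly computes the base metric on the current (shrinking) network,
#' records the value of the most central node, removes that node and
#' iterates until the network is empty. Each node keeps the value it had at
#' its own removal; ties are broken by ascending patient id. The last node's
#' value is computed on the singleton graph (0 for both base metrics).
#'
#' @param psn a [new_psn()] object.
#' @param base base metric: `"weighted_degree"` or `"local_clustering"`
#'   (Onnela weighted clustering).
#' @return named numeric vector over patients.
#' @export
iterative_centrality <- function(psn, base = c("weighted_degree", "local_clustering")) {
  base <- match.arg(base)
  w <- psn$w
  ids <- psn$patient_ids
  remaining <- seq_along(ids)
  out <- setNames(numeric(length(ids)), ids)
  while (length(remaining) > 0) {
    sub <- w[remaining, remaining, drop = FALSE]
    vals <- if (base == "weighted_degree") rowSums(sub) else
      as.numeric(.onnela_clustering(sub))
    pick <- order(-vals, ids[remaining])[1]
    out[ids[remaining][pick]] <- vals[pick]
    remaining <- remaining[-pick]
  }
  out
}

#' Column-wise z-score standardization
#'
#' Standardizes every column to zero mean and unit standard deviation (the
#' population SD, i.e. the `1/n` variance denominator, so a standardized
#' column has exactly unit mean square). Zero-variance columns are set to
#' all zeros with a warning. Idempotent on already standardized matrices.
#'
#' @param m numeric matrix with at least 2 rows.
#' @return standardized matrix; `standardized` attribute set to `TRUE`,
#'   other attributes (e.g. `family`) preserved.
#' @export
standardize_features <- function(m) {
  .assert(is.matrix(m) && nrow(m) >= 2, "need a matrix with >= 2 rows")
  mu <- colMeans(m)
  s <- sqrt(colMeans(sweep(m, 2, mu, "-")^2))
  degen <- !is.finite(s) | s < 1e-12
  if (any(degen))
    warning(sprintf("%d zero-variance column(s) set to all zeros", sum(degen)))
  s[degen] <- 1
  out <- sweep(sweep(m, 2, mu, "-"), 2, s, "/")
  out[, degen] <- 0
  attr(out, "family") <- attr(m, "family")
  attr(out, "standardized") <- TRUE
  out
}
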