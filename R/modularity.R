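# canonicalize module labels: largest module gets label 1, ties by first
# appearance; returns integer labels 1..k
.canonical_labels <- function(lab) {
  tab <- sort(table(lab), decreasing = TRUE)
  map <- setNames(seq_along(tab), names(tab))
  as.integer(map[as.character(lab)])
}

.new_partition <- function(method, assignment, criterion_value) {
  structure(list(method = method,
                 k = length(unique(assignment)),
                 assignment = assignment,
                 criterion_value = criterion_value),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("%s partition: k=%d (criterion %.4g)\n", x$method, x$k,
              x$criterion_value))
  invisible(x)
}

#' Spectral partitions of a PSN
#'
#' Normalized-Laplacian spectral clustering for each candidate module count
#' `k`. The quality criterion is the eigengap `lambda[k+1] - lambda[k]` of
#' the normalized Laplacian; the best `k` and every `k` whose eigengap is
#' within `tolerance` (fractionally) of the best are retained, since several
#' partitions can be near-optimal. Labels are canonicalized by module size.
#'
#' @param psn a [new_psn()] object with at least 4 patients.
#' @param k_range candidate module counts (default `2:10`); clipped with a
#'   warning when it exceeds `n - 1`.
#' @param tolerance near-optimality margin: retain `k` with eigengap
#'   `>= (1 - tolerance) * best` (default 0.05). `Inf` retains all.
#' @param rng_seed seed for the k-means step.
#' @return list of `module_partition` objects (best first).
#' @export
spectral_partitions <- function(psn, k_range = 2:10, tolerance = 0.05,
                                rng_seed = 1L) {
  .assert(inherits(psn, "psn"), "psn must be a psn object")
  w <- psn$w
  n <- nrow(w)
  .assert(n >= 4, "need at least 4 patients")
  if (max(k_range) > n - 1) {
    warning("k_range exceeds n - 1; clipping")
    k_range <- k_range[k_range <= n - 1]
  }
  d <- rowSums(w)
  d[d <= 0] <- 1e-12
  dh <- 1 / sqrt(d)
  Lsym <- diag(n) - (dh * w) %*% diag(dh)   # I - D^{-1/2} W D^{-1/2}
  es <- eigen((Lsym + t(Lsym)) / 2, symmetric = TRUE)
  lambda <- rev(es$values)                   # ascending
  vecs <- es$vectors[, rev(seq_len(n)), drop = FALSE]
  gaps <- vapply(k_range, function(k) lambda[k + 1] - lambda[k], numeric(1))
  best <- max(gaps)
  keep <- if (is.infinite(tolerance)) rep(TRUE, length(k_range)) else
    gaps >= (1 - tolerance) * best
  ks <- k_range[keep][order(-gaps[keep])]
  lapply(seq_along(ks), function(i) {
    k <- ks[i]
    u <- vecs[, seq_len(k), drop = FALSE]
    nr <- sqrt(rowSums(u^2))
    nr[nr == 0] <- 1
    u <- u / nr
    set.seed(derive_seed(rng_seed, "spectral", k))
    cl <- kmeans(u, centers = k, nstart = 10, iter.max = 100)$cluster
    lab <- .canonical_labels(cl)
    names(lab) <- psn$patient_ids
    .new_partition("spectral", lab, gaps[k_range == k])
  })
}

# Poisson degree-corrected SBM profile log-likelihood from block aggregates:
# (1/2) * sum_rs m_rs * log(m_rs / (kappa_r kappa_s)), with m_rs the total
# inter-block weight and kappa_r the block total degree.
.dcsbm_obj <- function(M, kap) {
  terms <- M * log(M / outer(kap, kap))
  terms[M == 0] <- 0
  sum(terms) / 2
}

.dcsbm_loglik <- function(w, lab) {
  k <- max(lab)
  Z <- matrix(0, nrow(w), k)
  Z[cbind(seq_len(nrow(w)), lab)] <- 1
  M <- t(Z) %*% w %*% Z
  .dcsbm_obj(M, colSums(M))
}

# greedy best-move node relabeling with incremental aggregate updates;
# returns updated labels
.dcsbm_sweep <- function(w, lab, k) {
  n <- nrow(w)
  Z <- matrix(0, n, k)
  Z[cbind(seq_len(n), lab)] <- 1
  M <- t(Z) %*% w %*% Z
  kap <- colSums(M)
  deg <- rowSums(w)
  size <- tabulate(lab, k)
  cur <- .dcsbm_obj(M, kap)
  for (i in sample.int(n)) {
    r <- lab[i]
    if (size[r] == 1) next                       # keep blocks non-empty
    ci <- as.numeric(w[i, ] %*% Z)               # weight from i to each block
    best_gain <- 1e-12
    best_s <- r
    for (s in seq_len(k)) {
      if (s == r) next
      M2 <- M
      M2[r, ] <- M2[r, ] - ci
      M2[, r] <- M2[, r] - ci
      M2[s, ] <- M2[s, ] + ci
      M2[, s] <- M2[, s] + ci
      M2[M2 < 0] <- 0
      kap2 <- kap
      kap2[r] <- kap2[r] - deg[i]
      kap2[s] <- kap2[s] + deg[i]
      gain <- .dcsbm_obj(M2, kap2) - cur
      if (gain > best_gain) {
        best_gain <- gain
        best_s <- s
      }
    }
    if (best_s != r) {
      s <- best_s
      lab[i] <- s
      Z[i, r] <- 0
      Z[i, s] <- 1
      size[r] <- size[r] - 1
      size[s] <- size[s] + 1
      M <- t(Z) %*% w %*% Z                     # exact refresh, O(n^2 k)
      M[M < 0] <- 0
      kap <- colSums(M)
      cur <- .dcsbm_obj(M, kap)
    }
  }
  lab
}

#' Stochastic block model partitions of a PSN
#'
#' Fits a degree-corrected (Poisson, weighted) stochastic block model for
#' each candidate number of blocks by greedy likelihood maximization from a
#' spectral initialization. Model selection uses a description-length style
#' criterion, `-logLik + (k (k + 1) / 2) * log(n_pairs)`; a single-block
#' model is always evaluated as the null baseline, so uniform networks
#' prefer one block. Near-optimal `k`s (within `tolerance` of the best
#' description length, relative to the spread across candidates) are
#' retained. Deterministic for a given seed.
#'
#' @param psn a [new_psn()] object with at least 4 patients.
#' @param k_range candidate block counts (default `2:10`).
#' @param tolerance near-optimality margin on the description length
#'   (default 0.05 of the candidate spread).
#' @param sweeps maximum greedy sweeps per fit.
#' @param rng_seed seed for the sweep order and initialization.
#' @return list of `module_partition` objects (best first); empty list with
#'   a warning if every fit fails.
#' @export
sbm_partitions <- function(psn, k_range = 2:10, tolerance = 0.05, sweeps = 10,
                           rng_seed = 1L) {
  .assert(inherits(psn, "psn"), "psn must be a psn object")
  w <- psn$w
  n <- nrow(w)
  .assert(n >= 4, "need at least 4 patients")
  k_range <- k_range[k_range <= n - 1 & k_range >= 2]
  n_pairs <- n * (n - 1) / 2
  fits <- list()
  # null baseline: one block
  lab1 <- setNames(rep(1L, n), psn$patient_ids)
  fits[["1"]] <- list(lab = lab1,
                      dl = -.dcsbm_loglik(w, lab1) + log(n_pairs))
  spec_init <- tryCatch(
    spectral_partitions(psn, k_range = k_range, tolerance = Inf,
                        rng_seed = derive_seed(rng_seed, "sbm-init")),
    error = function(e) NULL)
  for (k in k_range) {
    fit <- tryCatch({
      init <- NULL
      if (!is.null(spec_init))
        for (p in spec_init) if (p$k == k) init <- p$assignment
      if (is.null(init) || length(unique(init)) < k) {
        set.seed(derive_seed(rng_seed, "sbm-rand", k))
        init <- sample(rep_len(seq_len(k), n))
      }
      lab <- as.integer(init)
      set.seed(derive_seed(rng_seed, "sbm-sweep", k))
      for (s in seq_len(sweeps)) {
        new_lab <- .dcsbm_sweep(w, lab, k)
        if (identical(new_lab, lab)) break
        lab <- new_lab
      }
      dl <- -.dcsbm_loglik(w, lab) + (k * (k + 1) / 2) * log(n_pairs)
      list(lab = setNames(lab, psn$patient_ids), dl = dl)
    }, error = function(e) NULL)
    if (!is.null(fit)) fits[[as.character(k)]] <- fit
  }
  if (length(fits) == 0) {
    warning("all SBM fits failed; returning empty partition list")
    return(list())
  }
  dls <- vapply(fits, `[[`, numeric(1), "dl")
  spread <- max(dls) - min(dls)
  keep <- if (spread <= 0) dls == min(dls) else
    (dls - min(dls)) <= tolerance * spread
  ord <- order(dls)
  ord <- ord[keep[ord]]
  lapply(ord, function(i) {
    lab <- .canonical_labels(fits[[i]]$lab)
    names(lab) <- psn$patient_ids
    .new_partition("sbm", lab, fits[[i]]$dl)
  })
}

#' Encode module memberships as binary features
#'
#' One-hot encodes each partition and concatenates the blocks: the feature
#' matrix has `sum(k_s)` columns over the partition set, and within each
#' partition's block every row sums to exactly one.
#'
#' @param partitions non-empty list of `module_partition` objects over the
#'   same node set.
#' @return patients x `sum(k_s)` binary matrix, `family` attribute
#'   `"modularity"`.
#' @export
encode_membership <- function(partitions) {
  .assert(length(partitions) >= 1, "need at least one partition")
  ids <- names(partitions[[1]]$assignment)
  blocks <- lapply(seq_along(partitions), function(s) {
    p <- partitions[[s]]
    .assert(setequal(names(p$assignment), ids),
            "partitions cover inconsistent node sets")
    a <- p$assignment[ids]
    z <- matrix(0L, length(ids), p$k,
                dimnames = list(ids, sprintf("%s%d_k%d_m%d", p$method, s, p$k,
                                             seq_len(p$k))))
    z[cbind(seq_along(ids), a)] <- 1L
    z
  })
  out <- do.call(cbind, blocks)
  attr(out, "family") <- "modularity"
  out
}
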