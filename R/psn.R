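#' Construct a Patient Similarity Network object
#'
#' A PSN is a complete weighted undirected graph over patients: a symmetric
#' weight matrix with entries in `[0, 1]` and a zero diagonal, plus metadata
#' (construction tag, soft-threshold power, source tag, scale-free fit).
#'
#' @param w symmetric numeric matrix, patients x patients, weights in
#'   `[0, 1]`, zero diagonal, patient ids as dimnames.
#' @param tag construction tag: `"WGCNA"`, `"correl"` or `"fused"`.
#' @param beta soft-threshold power used (NA for fused networks).
#' @param source_tag omics source the network was built from.
#' @param fit_index truncated scale-free fit index, if evaluated.
#' @return a `psn` object.
#' @export
new_psn <- function(w, tag, beta = NA_real_, source_tag = NA_character_,
                    fit_index = NA_real_) {
  .assert(is.matrix(w) && nrow(w) == ncol(w), "w must be a square matrix")
  .assert(!is.null(rownames(w)), "w must carry patient ids as dimnames")
  .assert(!anyNA(w), "w must be complete (no missing weights)")
  .assert(max(abs(w - t(w))) < 1e-10, "w must be symmetric")
  .assert(all(diag(w) == 0), "w must have a zero diagonal")
  .assert(min(w) >= -1e-12 && max(w) <= 1 + 1e-12, "weights must lie in [0, 1]")
  w[w < 0] <- 0
  w[w > 1] <- 1
  w <- (w + t(w)) / 2
  structure(list(w = w,
                 patient_ids = rownames(w),
                 meta = list(tag = tag, beta = beta, source_tag = source_tag,
                             fit_index = fit_index)),
            class = "psn")
}

#' @export
print.psn <- function(x, ...) {
  cat(sprintf("patient similarity network: %d patients, tag=%s, beta=%s, fit=%s\n",
              length(x$patient_ids), x$meta$tag,
              format(x$meta$beta), format(x$meta$fit_index)))
  invisible(x)
}

#' Pearson correlations between patient profiles
#'
#' Computes the Pearson correlation coefficient between every pair of patient
#' profiles (rows) across features. Duplicate patient columns should be
#' averaged upstream; zero-variance profiles are an error since their
#' correlation is undefined.
#'
#' @param m patients x features matrix (at least 2 features, no missing
#'   values).
#' @return symmetric patients x patients correlation matrix (unit diagonal).
#' @export
pearson_psn <- function(m) {
  .check_omics(m)
  .assert(ncol(m) >= 2, "need at least 2 features to correlate profiles")
  .assert(!anyNA(m), "matrix contains missing values; run drop_missing_features first")
  sds <- apply(m, 1, sd)
  bad <- rownames(m)[sds == 0]
  .assert(length(bad) == 0, "zero-variance profile for patient(s): %s",
          paste(bad, collapse = ", "))
  cm <- cor(t(m))
  (cm + t(cm)) / 2
}

#' Soft-threshold a correlation matrix into a PSN
#'
#' Min-max normalizes the off-diagonal correlations to `[0, 1]` and raises
#' them to the power `beta`, the WGCNA-style soft threshold that pushes a
#' network toward scale-free topology without pruning edges:
#' `w = ((c - min(C)) / (max(C) - min(C)))^beta`, with `C` the set of all
#' off-diagonal correlations. `beta = 1` is the plain normalized-correlation
#' control (tag `"correl"`); `beta > 1` is tagged `"WGCNA"`.
#'
#' @param cm symmetric correlation matrix with patient ids as dimnames.
#' @param beta positive power.
#' @param source_tag optional source label stored in the network metadata.
#' @return a [new_psn()] object.
#' @export
rescale_correlations <- function(cm, beta, source_tag = NA_character_) {
  .assert(is.matrix(cm) && nrow(cm) == ncol(cm) && nrow(cm) >= 2,
          "cm must be a square matrix over >= 2 patients")
  .assert(beta >= 1, "beta must be >= 1")
  off <- cm
  diag(off) <- NA
  mn <- min(off, na.rm = TRUE)
  mx <- max(off, na.rm = TRUE)
  .assert(mx - mn > 1e-12, "degenerate correlation range: max(C) == min(C)")
  w <- ((cm - mn) / (mx - mn))^beta
  diag(w) <- 0
  new_psn(w, tag = if (beta > 1) "WGCNA" else "correl", beta = beta,
          source_tag = source_tag)
}

#' Truncated scale-free fit index of a connectivity vector
#'
#' Bins the connectivities into equal-width bins, then regresses
#' `log10(frequency)` jointly on `log10(mean connectivity)` and the mean
#' connectivity of each non-empty bin (truncated exponential power law) and
#' returns the regression R-squared.
#'
#' @param k numeric vector of node connectivities.
#' @param bins number of equal-width bins (default 10).
#' @return fit index in `[0, 1]`.
#' @export
scale_free_fit_index <- function(k, bins = 10) {
  .assert(length(k) >= 4, "need at least 4 nodes")
  if (max(k) - min(k) < 1e-12) {
    warning("all connectivities equal; scale-free fit undefined, returning 0")
    return(0)
  }
  breaks <- seq(min(k), max(k), length.out = bins + 1)
  idx <- findInterval(k, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  dk <- tapply(k, idx, mean)
  pk <- tapply(k, idx, length) / length(k)
  if (length(dk) < 4) {
    warning("fewer than 4 occupied connectivity bins; fit index unreliable")
    if (length(dk) < 3) return(0)
  }
  fit <- lm(log10(pk) ~ log10(dk) + dk)
  r2 <- summary(fit)$r.squared
  max(0, min(1, r2))
}

#' Truncated scale-free fit index of a PSN
#'
#' Node connectivity is the weighted degree (row sum of the weight matrix);
#' the index is [scale_free_fit_index()] of those connectivities. For small
#' networks the bin count is reduced to roughly one bin per three nodes.
#'
#' @param psn a [new_psn()] object.
#' @param bins number of equal-width connectivity bins (default 10).
#' @return fit index in `[0, 1]`.
#' @export
scale_free_fit <- function(psn, bins = 10) {
  .assert(inherits(psn, "psn"), "psn must be a psn object")
  n <- nrow(psn$w)
  if (n < 3 * bins) {
    bins <- max(3, floor(n / 3))
    message(sprintf("small network: reducing connectivity bins to %d", bins))
  }
  scale_free_fit_index(rowSums(psn$w), bins = bins)
}

#' Select the soft-threshold power by scale-free fit
#'
#' Evaluates the candidate powers in ascending order and returns the first
#' whose truncated scale-free fit index reaches `scale_free_target`. If no
#' candidate reaches the target, the candidate with the maximal fit is
#' returned and a structured warning (class
#' `psntopo_no_scale_free_beta`) is raised.
#'
#' @param cm symmetric patient correlation matrix.
#' @param beta_candidates ascending candidate powers (default
#'   `c(2, 4, 6, 8, 10, 12)`).
#' @param scale_free_target required fit index (default 0.90).
#' @param bins connectivity bins for the fit.
#' @param source_tag source label forwarded to the network metadata.
#' @return list with `beta`, `fit_index`, `psn` (metadata records both) and
#'   `scan`, a data.frame of the evaluated candidates and their fits.
#' @export
select_beta <- function(cm, beta_candidates = c(2, 4, 6, 8, 10, 12),
                        scale_free_target = 0.90, bins = 10,
                        source_tag = NA_character_) {
  .assert(length(beta_candidates) >= 1 && !is.unsorted(beta_candidates),
          "beta_candidates must be sorted ascending")
  .assert(scale_free_target >= 0 && scale_free_target <= 1,
          "scale_free_target must be in [0, 1]")
  fits <- numeric(0)
  nets <- list()
  chosen <- NA
  for (b in beta_candidates) {
    net <- rescale_correlations(cm, b, source_tag = source_tag)
    fit <- scale_free_fit(net, bins = bins)
    fits[as.character(b)] <- fit
    nets[[as.character(b)]] <- net
    if (fit >= scale_free_target) {
      chosen <- b
      break
    }
  }
  if (is.na(chosen)) {
    chosen <- beta_candidates[which.max(fits)]
    warning(structure(
      class = c("psntopo_no_scale_free_beta", "warning", "condition"),
      list(message = sprintf(
             "no candidate beta reaches scale-free fit %.2f (best: beta=%s, fit=%.3f)",
             scale_free_target, chosen, max(fits)),
           call = sys.call(-1))))
  }
  psn <- nets[[as.character(chosen)]]
  psn$meta$beta <- chosen
  psn$meta$fit_index <- unname(fits[as.character(chosen)])
  list(beta = chosen, fit_index = unname(fits[as.character(chosen)]),
       psn = psn,
       scan = data.frame(beta = as.numeric(names(fits)), fit = unname(fits)))
}

# SNF full kernel: off-diagonal mass 1/2 spread by row similarity, diag 1/2
.snf_full_kernel <- function(w) {
  d <- w
  diag(d) <- 0
  rs <- rowSums(d)
  rs[rs == 0] <- 1
  p <- d / (2 * rs)
  diag(p) <- 0.5
  p
}

# SNF local kernel: row-normalized weights restricted to the K nearest
# neighbours of each node
.snf_local_kernel <- function(w, K) {
  n <- nrow(w)
  s <- matrix(0, n, n, dimnames = dimnames(w))
  for (i in seq_len(n)) {
    wi <- w[i, ]
    wi[i] <- -Inf
    nbr <- order(wi, decreasing = TRUE)[seq_len(K)]
    s[i, nbr] <- w[i, nbr] / sum(w[i, nbr])
  }
  s
}

#' Fuse Patient Similarity Networks (SNF)
#'
#' Similarity Network Fusion: each network is converted into a row-normalized
#' full kernel `P` and a K-nearest-neighbour local kernel `S`; each `P` is
#' then iteratively cross-diffused through the others,
#' `P_v <- S_v %*% mean(P_u, u != v) %*% t(S_v)`, symmetrized and
#' renormalized, for `T` rounds. The output is the symmetrized average of the
#' fused kernels, min-max rescaled to `[0, 1]` with a zero diagonal.
#'
#' @param psns list of at least two [new_psn()] objects over identical
#'   patient id sets.
#' @param K number of neighbours for the local kernel (default 10).
#' @param T number of fusion iterations (default 50).
#' @param trace if `TRUE`, attach the per-iteration Frobenius change between
#'   successive iterates as attribute `"delta"` of the result.
#' @return a fused `psn` (tag `"fused"`).
#' @export
fuse_networks <- function(psns, K = 10, T = 50, trace = FALSE) {
  .assert(length(psns) >= 2, "need at least two networks to fuse")
  .assert(all(vapply(psns, inherits, logical(1), "psn")), "inputs must be psn objects")
  ids <- psns[[1]]$patient_ids
  for (v in seq_along(psns)) {
    dv <- union(setdiff(psns[[v]]$patient_ids, ids), setdiff(ids, psns[[v]]$patient_ids))
    .assert(length(dv) == 0,
            "patient sets differ between networks (network %d): %s",
            v, paste(dv, collapse = ", "))
    psns[[v]]$w <- psns[[v]]$w[ids, ids]
  }
  n <- length(ids)
  .assert(K >= 1 && K < n, "K must be in [1, n_patients)")
  .assert(T >= 1, "T must be >= 1")
  m <- length(psns)
  P <- lapply(psns, function(p) .snf_full_kernel(p$w))
  S <- lapply(psns, function(p) .snf_local_kernel(p$w, K))
  delta <- numeric(T)
  for (it in seq_len(T)) {
    Pnew <- vector("list", m)
    for (v in seq_len(m)) {
      avg <- Reduce(`+`, P[-v]) / (m - 1)
      Q <- S[[v]] %*% avg %*% t(S[[v]])
      Q <- (Q + t(Q)) / 2
      Pnew[[v]] <- .snf_full_kernel(Q)
    }
    delta[it] <- sqrt(sum((Reduce(`+`, Pnew) / m - Reduce(`+`, P) / m)^2))
    P <- Pnew
  }
  fused <- Reduce(`+`, P) / m
  fused <- (fused + t(fused)) / 2
  diag(fused) <- NA
  mn <- min(fused, na.rm = TRUE)
  mx <- max(fused, na.rm = TRUE)
  .assert(mx - mn > 1e-15, "degenerate fused network")
  fused <- (fused - mn) / (mx - mn)
  diag(fused) <- 0
  dimnames(fused) <- list(ids, ids)
  out <- new_psn(fused, tag = "fused")
  if (trace) attr(out, "delta") <- delta
  out
}

#' Convert a PSN to an igraph graph
#'
#' Zero-weight pairs become non-edges; all positive weights are kept.
#'
#' @param psn a [new_psn()] object.
#' @return an undirected weighted `igraph` graph.
#' @export
psn_to_igraph <- function(psn) {
  igraph::graph_from_adjacency_matrix(psn$w, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Write a PSN as a 3-column weighted edge list with a YAML meta sidecar
#'
#' @param psn a [new_psn()] object.
#' @param path output TSV (columns `id_a`, `id_b`, `weight`, header line);
#'   metadata goes to `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_psn_edgelist <- function(psn, path) {
  idx <- which(upper.tri(psn$w), arr.ind = TRUE)
  df <- data.frame(id_a = psn$patient_ids[idx[, 1]],
                   id_b = psn$patient_ids[idx[, 2]],
                   weight = psn$w[idx], stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(psn$meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a PSN from a weighted edge list written by [write_psn_edgelist()]
#'
#' @param path edge-list TSV; the `<path>.yaml` sidecar is read when present.
#' @return a `psn` object.
#' @export
read_psn_edgelist <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "numeric"))
  ids <- sort(unique(c(df$id_a, df$id_b)))
  w <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  w[cbind(df$id_a, df$id_b)] <- df$weight
  w[cbind(df$id_b, df$id_a)] <- df$weight
  meta <- if (file.exists(paste0(path, ".yaml"))) yaml::read_yaml(paste0(path, ".yaml")) else list()
  new_psn(w,
          tag = if (!is.null(meta$tag)) meta$tag else "unknown",
          beta = if (!is.null(meta$beta)) meta$beta else NA_real_,
          source_tag = if (!is.null(meta$source_tag)) meta$source_tag else NA_character_,
          fit_index = if (!is.null(meta$fit_index)) meta$fit_index else NA_real_)
}

#' Write a PSN as GraphML
#' @param psn a [new_psn()] object.
#' @param path output GraphML file.
#' @return `path`, invisibly.
#' @export
write_psn_graphml <- function(psn, path) {
  igraph::write_graph(psn_to_igraph(psn), path, format = "graphml")
  invisible(path)
}
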