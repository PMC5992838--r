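#' Drop features with missing values
#'
#' Removes every feature (column) that has at least one missing entry;
#' feature order is preserved.
#'
#' @param m patients x features matrix.
#' @return the matrix restricted to complete features.
#' @export
drop_missing_features <- function(m) {
  .check_omics(m)
  keep <- colSums(is.na(m)) == 0
  .assert(any(keep), "no features remain after dropping missing features")
  out <- m[, keep, drop = FALSE]
  attr(out, "source_tag") <- attr(m, "source_tag")
  out
}

#' Rank-sum p-values per feature between two label groups
#'
#' Two-sided Wilcoxon rank-sum test of each feature between the `labels == 1`
#' and `labels == 0` groups. The exact distribution is used when both groups
#' have at most `exact_max` patients and the feature has no ties; otherwise
#' the normal approximation with tie correction is used.
#'
#' @param m patients x features matrix.
#' @param labels 0/1 vector aligned with rows of `m`.
#' @param exact_max largest group size for which the exact test is attempted.
#' @return named vector of p-values, one per feature.
#' @export
rank_sum_pvalues <- function(m, labels, exact_max = 10) {
  .assert(length(labels) == nrow(m), "labels must align with patients")
  labels <- as.integer(labels)
  .assert(all(labels %in% c(0L, 1L)), "labels must be 0/1")
  .assert(any(labels == 0) && any(labels == 1),
          "both classes must be non-empty")
  g1 <- labels == 1
  use_exact <- sum(g1) <= exact_max && sum(!g1) <= exact_max
  p <- vapply(seq_len(ncol(m)), function(j) {
    suppressWarnings(
      wilcox.test(m[g1, j], m[!g1, j], exact = use_exact, correct = !use_exact)$p.value
    )
  }, numeric(1))
  p[!is.finite(p)] <- 1     # fully tied feature: no evidence either way
  names(p) <- colnames(m)
  p
}

#' Wilcoxon-based feature selection
#'
#' Keeps the features that behave differently between the two label groups:
#' either all features significant at `p_threshold`, or the fixed
#' `top_fraction` with the smallest p-values regardless of significance.
#' When `train_ids` is given, the test statistics are computed on those
#' patients only and the selection is then applied to the full matrix
#' (leakage-free mode); with `train_ids = NULL` all patients are used.
#'
#' @param m patients x features matrix.
#' @param labels 0/1 vector aligned with rows of `m` (or with `train_ids`
#'   when those are given as the names of `labels`).
#' @param mode `"significant"` (p < threshold) or `"top_fraction"`.
#' @param p_threshold significance cut-off (default 0.05).
#' @param top_fraction fraction of features kept in top-fraction mode
#'   (default 0.10); `ceiling(top_fraction * n_features)` features are kept,
#'   ties broken by feature id.
#' @param train_ids optional patient ids on which to compute the statistics.
#' @return the matrix restricted to selected features (original column order).
#' @export
wilcoxon_select <- function(m, labels,
                            mode = c("significant", "top_fraction"),
                            p_threshold = 0.05, top_fraction = 0.10,
                            train_ids = NULL) {
  mode <- match.arg(mode)
  .assert(p_threshold > 0 && p_threshold < 1, "p_threshold must be in (0, 1)")
  .assert(top_fraction > 0 && top_fraction < 1, "top_fraction must be in (0, 1)")
  fit_m <- m
  fit_lab <- labels
  if (!is.null(train_ids)) {
    .assert(all(train_ids %in% rownames(m)), "train_ids not all present")
    fit_m <- m[train_ids, , drop = FALSE]
    fit_lab <- if (!is.null(names(labels))) labels[train_ids] else labels
  }
  p <- rank_sum_pvalues(fit_m, fit_lab)
  sel <- if (mode == "significant") {
    names(p)[p < p_threshold]
  } else {
    k <- ceiling(top_fraction * length(p))
    names(p)[order(p, names(p))][seq_len(k)]
  }
  .assert(length(sel) > 0, "no features selected")
  out <- m[, colnames(m) %in% sel, drop = FALSE]
  attr(out, "source_tag") <- attr(m, "source_tag")
  out
}

#' Keep the most varying features
#'
#' Ranks features by sample variance and keeps the top fraction; ties are
#' broken by feature id. Selection is independent of any clinical endpoint.
#'
#' @param m patients x features matrix (at least 10 features).
#' @param top_fraction fraction kept (default 0.10);
#'   `ceiling(top_fraction * n_features)` features survive.
#' @param train_ids optional patient ids on which variances are computed.
#' @return the matrix restricted to the selected features.
#' @export
variance_select <- function(m, top_fraction = 0.10, train_ids = NULL) {
  .assert(ncol(m) >= 10, "variance_select needs at least 10 features")
  .assert(top_fraction > 0 && top_fraction <= 1, "top_fraction must be in (0, 1]")
  fit_m <- if (is.null(train_ids)) m else m[train_ids, , drop = FALSE]
  v <- apply(fit_m, 2, var)
  k <- ceiling(top_fraction * ncol(m))
  sel <- colnames(m)[order(-v, colnames(m))][seq_len(k)]
  out <- m[, colnames(m) %in% sel, drop = FALSE]
  attr(out, "source_tag") <- attr(m, "source_tag")
  out
}

#' PCA pseudo-features explaining a target share of variance
#'
#' Centered principal component analysis; returns the smallest set of leading
#' components whose cumulative explained variance ratio exceeds
#' `variance_target`. Pseudo-features are named `PC1..PCk`.
#'
#' @param m patients x features matrix (at least 2 patients).
#' @param variance_target cumulative explained-variance threshold in `[0, 1)`,
#'   default 0.90.
#' @param train_ids optional patient ids on which the rotation is fitted; the
#'   projection is then applied to all patients.
#' @return patients x components score matrix with an `explained` attribute
#'   (cumulative explained variance ratio of the retained set).
#' @export
pca_reduce <- function(m, variance_target = 0.90, train_ids = NULL) {
  .assert(nrow(m) >= 2, "pca_reduce needs at least 2 patients")
  .assert(variance_target >= 0 && variance_target < 1,
          "variance_target must be in [0, 1)")
  fit_m <- if (is.null(train_ids)) m else m[train_ids, , drop = FALSE]
  tot <- sum(apply(fit_m, 2, var))
  .assert(tot > 0, "zero-variance matrix: PCA undefined")
  pc <- prcomp(fit_m, center = TRUE, scale. = FALSE)
  expl <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- which(expl > variance_target)[1]
  if (is.na(k)) k <- length(expl)
  scores <- scale(m, center = pc$center, scale = FALSE) %*% pc$rotation[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  attr(scores, "explained") <- expl[k]
  attr(scores, "source_tag") <- attr(m, "source_tag")
  scores
}

#' Apply a named dimension-reduction strategy
#'
#' Dispatches to the four reduction strategies (`wilcoxon_p`,
#' `wilcoxon_top`, `variance_top`, `pca_var`) or returns the matrix
#' unchanged (`none`).
#'
#' @param m patients x features matrix.
#' @param strategy one of `"wilcoxon_p"`, `"wilcoxon_top"`, `"variance_top"`,
#'   `"pca_var"`, `"none"`.
#' @param labels 0/1 endpoint labels (required for the Wilcoxon strategies).
#' @param p_threshold,top_fraction,variance_target strategy parameters.
#' @param train_ids optional ids defining the fit scope (statistics computed
#'   on these patients only).
#' @return the reduced matrix.
#' @export
reduce_features <- function(m, strategy = c("none", "wilcoxon_p", "wilcoxon_top",
                                            "variance_top", "pca_var"),
                            labels = NULL, p_threshold = 0.05,
                            top_fraction = 0.10, variance_target = 0.90,
                            train_ids = NULL) {
  strategy <- match.arg(strategy)
  switch(strategy,
    none = m,
    wilcoxon_p = wilcoxon_select(m, labels, "significant",
                                 p_threshold = p_threshold, train_ids = train_ids),
    wilcoxon_top = wilcoxon_select(m, labels, "top_fraction",
                                   top_fraction = top_fraction, train_ids = train_ids),
    variance_top = variance_select(m, top_fraction, train_ids = train_ids),
    pca_var = pca_reduce(m, variance_target, train_ids = train_ids))
}

#' Define the large and small patient cohorts
#'
#' The large cohort contains the patients covered by every source except the
#' last (the restricted source, e.g. a genomic assay run on a subset); the
#' small cohort contains the patients covered by every source. Both are
#' intersected with the clinical table and returned sorted.
#'
#' @param omics named list of patients x features matrices (the last entry is
#'   the restricted source).
#' @param clinical patients x endpoints 0/1 matrix.
#' @return list with sorted character vectors `large` and `small`.
#' @export
align_cohorts <- function(omics, clinical) {
  .assert(length(omics) >= 1, "need at least one omics source")
  ids <- lapply(omics, rownames)
  base <- if (length(ids) > 1) Reduce(intersect, ids[-length(ids)]) else ids[[1]]
  large <- sort(intersect(base, rownames(clinical)))
  small <- sort(intersect(Reduce(intersect, ids), rownames(clinical)))
  .assert(length(large) > 0, "no patient shared between sources and clinical table")
  if (length(small) == 0)
    warning("small cohort is empty: no patient carries every source")
  list(large = large, small = small)
}
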