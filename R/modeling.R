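#' Stratified train/test split
#'
#' Splits patients into train and test halves per class:
#' `ceiling(fraction * n_class)` patients of each class are drawn into the
#' training set (so train/test class proportions match within one patient),
#' the rest form the test set. Deterministic from the seed.
#'
#' @param labels named 0/1 vector (names = patient ids).
#' @param fraction training fraction (default 0.5).
#' @param rng_seed integer seed.
#' @return a `split_spec`: list with `train`, `test` (character ids),
#'   `stratified = TRUE` and `rng_seed`.
#' @export
stratified_split <- function(labels, fraction = 0.5, rng_seed = 1L) {
  .assert(!is.null(names(labels)), "labels must be named by patient id")
  labels <- setNames(as.integer(labels), names(labels))
  .assert(all(labels %in% 0:1), "labels must be 0/1")
  .assert(fraction > 0 && fraction < 1, "fraction must be in (0, 1)")
  counts <- table(labels)
  .assert(length(counts) == 2, "both classes must be present")
  .assert(min(counts) >= 2, "a class with a single member cannot be split")
  set.seed(as.integer(rng_seed))
  train <- character(0)
  for (cl in c(0L, 1L)) {
    ids <- names(labels)[labels == cl]
    train <- c(train, sample(ids, ceiling(fraction * length(ids))))
  }
  train <- sort(train)
  structure(list(train = train, test = sort(setdiff(names(labels), train)),
                 stratified = TRUE, rng_seed = as.integer(rng_seed)),
            class = "split_spec")
}

#' Confusion-table performance metrics
#'
#' Accuracy, balanced accuracy (mean of sensitivity and specificity) and the
#' Matthews correlation coefficient of binary predictions, together with the
#' confusion counts. MCC is defined as 0 when any marginal of the confusion
#' table is empty.
#'
#' @param y_true,y_pred equal-length 0/1 vectors.
#' @return a `performance_report`: list with `ACC`, `bACC`, `MCC`, `TP`,
#'   `FP`, `FN`, `TN`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  .assert(length(y_true) > 0, "empty input")
  .assert(length(y_true) == length(y_pred), "length mismatch")
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  .assert(all(c(y_true, y_pred) %in% 0:1), "inputs must be binary 0/1")
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  tn <- sum(y_true == 0 & y_pred == 0)
  n <- length(y_true)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  tnr <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)
  structure(list(ACC = (tp + tn) / n,
                 bACC = mean(c(tpr, tnr)),
                 MCC = mcc,
                 TP = tp, FP = fp, FN = fn, TN = tn),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("ACC=%.4f bACC=%.4f MCC=%.4f (TP=%d FP=%d FN=%d TN=%d)\n",
              x$ACC, x$bACC, x$MCC, x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

# shrinkage LDA on a pooled ridge-regularized covariance; used when the
# within-class covariance is singular (p >= n or collinear features)
.lda_shrinkage <- function(x, y, lambda = 0.2) {
  mu1 <- colMeans(x[y == 1, , drop = FALSE])
  mu0 <- colMeans(x[y == 0, , drop = FALSE])
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  xc <- x
  xc[y == 1, ] <- sweep(x[y == 1, , drop = FALSE], 2, mu1)
  xc[y == 0, ] <- sweep(x[y == 0, , drop = FALSE], 2, mu0)
  S <- crossprod(xc) / max(1, n1 + n0 - 2)
  target <- mean(diag(S))
  if (target <= 0) target <- 1
  S <- (1 - lambda) * S + lambda * target * diag(ncol(x))
  wvec <- solve(S, mu1 - mu0)
  b <- as.numeric(-0.5 * crossprod(mu1 + mu0, wvec)) + log(n1 / n0)
  list(w = wvec, b = b)
}

# fit one classifier on training rows; returns an object with a score()
# closure mapping a feature matrix to P(class 1)-like scores in [0, 1]
.fit_classifier <- function(x, y, algorithm, svm_kernel = "radial",
                            cost = 1, gamma = NULL, rng_seed = 1L) {
  y <- as.integer(y)
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  set.seed(as.integer(rng_seed))
  if (algorithm == "lda") {
    fit <- if (ncol(xs) < nrow(xs) - 2) {
      tryCatch(suppressWarnings(MASS::lda(xs, grouping = factor(y, levels = 0:1))),
               error = function(e) NULL)
    } else NULL
    if (is.null(fit)) {
      sh <- .lda_shrinkage(xs, y)
      score <- function(newx) {
        nx <- sweep(sweep(newx, 2, ctr), 2, scl, "/")
        as.numeric(1 / (1 + exp(-(nx %*% sh$w + sh$b))))
      }
    } else {
      score <- function(newx) {
        nx <- sweep(sweep(newx, 2, ctr), 2, scl, "/")
        as.numeric(predict(fit, nx)$posterior[, "1"])
      }
    }
  } else if (algorithm == "rf") {
    fit <- randomForest::randomForest(xs, factor(y, levels = 0:1), ntree = 500)
    score <- function(newx) {
      nx <- sweep(sweep(newx, 2, ctr), 2, scl, "/")
      as.numeric(predict(fit, nx, type = "prob")[, "1"])
    }
  } else if (algorithm == "svm") {
    if (is.null(gamma)) gamma <- 1 / ncol(xs)
    fit <- e1071::svm(xs, factor(y, levels = 0:1), kernel = svm_kernel,
                      cost = cost, gamma = gamma, probability = TRUE,
                      scale = FALSE)
    score <- function(newx) {
      nx <- sweep(sweep(newx, 2, ctr), 2, scl, "/")
      pr <- predict(fit, nx, probability = TRUE)
      as.numeric(attr(pr, "probabilities")[, "1"])
    }
  } else stop("unknown algorithm: ", algorithm)
  list(score = score, algorithm = algorithm, cost = cost, gamma = gamma)
}

# stratified fold assignment: named integer vector of fold ids
.stratified_folds <- function(labels, folds, rng_seed) {
  set.seed(as.integer(rng_seed))
  fold <- setNames(integer(length(labels)), names(labels))
  for (cl in unique(labels)) {
    ids <- names(labels)[labels == cl]
    fold[sample(ids)] <- rep_len(seq_len(folds), length(ids))
  }
  fold
}

#' Repeated stratified cross-validation
#'
#' `repeats` x `folds`-fold stratified cross-validation (default ten times
#' five-fold, i.e. 50 fits), re-randomized per repeat, returning the mean
#' and spread of balanced accuracy as an unbiased performance estimate.
#'
#' @param features patients x features matrix (rownames = ids).
#' @param labels named 0/1 vector.
#' @param algorithm `"lda"`, `"rf"` or `"svm"`.
#' @param repeats,folds cross-validation design (defaults 10 and 5).
#' @param svm_kernel,cost,gamma classifier parameters.
#' @param rng_seed integer seed.
#' @return list with `cv_mean_bACC`, `cv_sd_bACC` and `per_fold` (one row
#'   per fitted model).
#' @export
crossvalidate <- function(features, labels, algorithm = c("lda", "rf", "svm"),
                          repeats = 10, folds = 5, svm_kernel = "radial",
                          cost = 1, gamma = NULL, rng_seed = 1L) {
  algorithm <- match.arg(algorithm)
  labels <- setNames(as.integer(labels), names(labels))
  .assert(all(names(labels) %in% rownames(features)), "labels/features id mismatch")
  .assert(min(table(labels)) >= folds, "need at least `folds` members per class")
  rows <- list()
  for (r in seq_len(repeats)) {
    fold <- .stratified_folds(labels, folds, derive_seed(rng_seed, "cv", r))
    for (f in seq_len(folds)) {
      tr <- names(fold)[fold != f]
      te <- names(fold)[fold == f]
      fit <- .fit_classifier(features[tr, , drop = FALSE], labels[tr],
                             algorithm, svm_kernel, cost, gamma,
                             rng_seed = derive_seed(rng_seed, "cvfit", r, f))
      pred <- as.integer(fit$score(features[te, , drop = FALSE]) >= 0.5)
      rep_row <- compute_metrics(labels[te], pred)
      rows[[length(rows) + 1]] <- data.frame(rep = r, fold = f,
                                             bACC = rep_row$bACC)
    }
  }
  per_fold <- do.call(rbind, rows)
  list(cv_mean_bACC = mean(per_fold$bACC), cv_sd_bACC = sd(per_fold$bACC),
       per_fold = per_fold)
}

# exhaustive SVM grid search by internal cross-validation on the training
# set; grid cost = gamma = 2^(2p), p in {-4, -2, -1, 0, 1, 2, 4}; ties go to
# the first candidate in scan order (cost-major)
.svm_grid_search <- function(x, y, svm_kernel, folds = 5, rng_seed = 1L) {
  pgrid <- c(-4, -2, -1, 0, 1, 2, 4)
  costs <- 2^(2 * pgrid)
  gammas <- if (svm_kernel == "radial") 2^(2 * pgrid) else NA_real_
  best <- NULL
  for (cost in costs) {
    for (gamma in gammas) {
      cv <- crossvalidate(x, y, "svm", repeats = 1, folds = folds,
                          svm_kernel = svm_kernel, cost = cost,
                          gamma = if (is.na(gamma)) NULL else gamma,
                          rng_seed = derive_seed(rng_seed, "grid"))
      if (is.null(best) || cv$cv_mean_bACC > best$bACC + 1e-12)
        best <- list(cost = cost, gamma = gamma, bACC = cv$cv_mean_bACC)
    }
  }
  best
}

#' Train on the training split, score the test split
#'
#' Fits one classifier on the training patients only (feature scaling and
#' any tuning statistics are computed on the training rows, never on test
#' rows), then produces class-probability-like scores in `[0, 1]` for the
#' test patients and a [compute_metrics()] report at threshold 0.5.
#'
#' @param features patients x features matrix.
#' @param labels named 0/1 vector covering train and test ids.
#' @param split a [stratified_split()] result.
#' @param algorithm `"lda"`, `"rf"` or `"svm"`.
#' @param svm_kernel `"radial"` or `"linear"`.
#' @param optimize if `TRUE` (SVM only), pick cost/gamma on the grid
#'   `2^(2p)`, `p` in `{-4, -2, -1, 0, 1, 2, 4}`, by internal
#'   cross-validation on the training set.
#' @param cost,gamma fixed SVM parameters when not optimizing.
#' @param rng_seed integer seed.
#' @return list with `scores` (named, test patients), `report`
#'   (`performance_report`), `algorithm` and `params`.
#' @export
train_predict <- function(features, labels, split,
                          algorithm = c("lda", "rf", "svm"),
                          svm_kernel = "radial", optimize = FALSE,
                          cost = 1, gamma = NULL, rng_seed = 1L) {
  algorithm <- match.arg(algorithm)
  .assert(inherits(split, "split_spec"), "split must be a split_spec")
  labels <- setNames(as.integer(labels), names(labels))
  tr <- split$train
  te <- split$test
  .assert(all(c(tr, te) %in% rownames(features)), "split ids missing from features")
  xtr <- features[tr, , drop = FALSE]
  ytr <- labels[tr]
  if (algorithm == "svm" && optimize) {
    g <- .svm_grid_search(xtr, ytr, svm_kernel,
                          rng_seed = derive_seed(rng_seed, "gridsearch"))
    cost <- g$cost
    gamma <- if (is.na(g$gamma)) NULL else g$gamma
  }
  fit <- .fit_classifier(xtr, ytr, algorithm, svm_kernel, cost, gamma,
                         rng_seed = derive_seed(rng_seed, "fit"))
  scores <- setNames(fit$score(features[te, , drop = FALSE]), te)
  report <- compute_metrics(labels[te], as.integer(scores >= 0.5))
  list(scores = scores, report = report, algorithm = algorithm,
       params = list(svm_kernel = if (algorithm == "svm") svm_kernel else NULL,
                     cost = if (algorithm == "svm") cost else NULL,
                     gamma = if (algorithm == "svm") gamma else NULL))
}

#' Weighted-voting integration of model predictions
#'
#' Combines per-patient scores from several models: weights are the given
#' performances normalized to sum to one, the consensus score is the
#' weighted mean of the model scores, and the binary prediction applies a
#' 0.5 threshold (consensus exactly at the threshold is called positive).
#'
#' @param score_sets list of named score vectors over the same patients.
#' @param performances non-negative model performances (e.g. cross-validated
#'   balanced accuracy), one per model; must not all be zero.
#' @param threshold consensus threshold in (0, 1), default 0.5.
#' @return list with `weights`, `consensus` (named scores) and `predictions`
#'   (named 0/1).
#' @export
weighted_vote <- function(score_sets, performances, threshold = 0.5) {
  .assert(length(score_sets) >= 1, "need at least one model")
  .assert(length(score_sets) == length(performances),
          "one performance per score set required")
  .assert(all(performances >= 0), "performances must be non-negative")
  .assert(sum(performances) > 0, "all performances are zero")
  .assert(threshold > 0 && threshold < 1, "threshold must be in (0, 1)")
  ids <- names(score_sets[[1]])
  .assert(!is.null(ids), "scores must be named by patient id")
  for (s in score_sets)
    .assert(setequal(names(s), ids), "score sets cover different patients")
  weights <- performances / sum(performances)
  mat <- vapply(score_sets, function(s) s[ids], numeric(length(ids)))
  consensus <- setNames(as.numeric(mat %*% weights), ids)
  list(weights = weights, consensus = consensus,
       predictions = setNames(as.integer(consensus >= threshold), ids))
}

#' Compare groups of model performances
#'
#' Two groups are compared by Welch's t-test; more than two by one-way ANOVA
#' followed by post-hoc Tukey HSD. Each pair is reported with its
#' balanced-accuracy gain `delta_bACC = mean(A) - mean(B)` and a
#' significance flag at p < 0.01.
#'
#' @param bacc_groups named list (>= 2 entries) of numeric vectors (>= 2
#'   values each), e.g. per-model balanced accuracies.
#' @param alpha significance level (default 0.01).
#' @return a `comparison_report`: data.frame with columns `group_a`,
#'   `group_b`, `delta_bACC`, `p_value`, `significant` (p may be `NA` when
#'   degenerate), plus attribute `anova_p` when more than two groups.
#' @export
compare_models <- function(bacc_groups, alpha = 0.01) {
  .assert(is.list(bacc_groups) && length(bacc_groups) >= 2,
          "need at least two named groups")
  .assert(!is.null(names(bacc_groups)) && all(nzchar(names(bacc_groups))),
          "groups must be named")
  .assert(all(vapply(bacc_groups, length, integer(1)) >= 2),
          "each group needs at least two values")
  nms <- names(bacc_groups)
  pairs <- combn(nms, 2)
  anova_p <- NA_real_
  if (length(bacc_groups) == 2) {
    p <- tryCatch(t.test(bacc_groups[[1]], bacc_groups[[2]])$p.value,
                  error = function(e) NA_real_)
    pvals <- setNames(p, paste(nms[2], nms[1], sep = "-"))
  } else {
    df <- data.frame(value = unlist(bacc_groups, use.names = FALSE),
                     group = factor(rep(nms, vapply(bacc_groups, length, integer(1)))))
    fit <- aov(value ~ group, data = df)
    anova_p <- tryCatch(summary(fit)[[1]][["Pr(>F)"]][1], error = function(e) NA_real_)
    tk <- tryCatch(TukeyHSD(fit)$group, error = function(e) NULL)
    pvals <- if (is.null(tk)) setNames(rep(NA_real_, ncol(pairs)), apply(pairs, 2, function(p)
      paste(p[2], p[1], sep = "-"))) else setNames(tk[, "p adj"], rownames(tk))
  }
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]
    b <- pairs[2, j]
    key <- if (paste(b, a, sep = "-") %in% names(pvals)) paste(b, a, sep = "-") else
      paste(a, b, sep = "-")
    p <- unname(pvals[key])
    data.frame(group_a = a, group_b = b,
               delta_bACC = mean(bacc_groups[[a]]) - mean(bacc_groups[[b]]),
               p_value = p,
               significant = !is.na(p) & p < alpha,
               stringsAsFactors = FALSE)
  }))
  attr(out, "anova_p") <- anova_p
  class(out) <- c("comparison_report", "data.frame")
  out
}
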