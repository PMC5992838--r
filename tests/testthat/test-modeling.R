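test_that("stratified splitting preserves class balance and determinism", {
  set.seed(1)
  labels <- setNames(c(rep(1, 60), rep(0, 40)), make_ids(100))
  sp <- stratified_split(labels, 0.5, rng_seed = 3)
  expect_length(sp$train, 50)
  expect_equal(sum(labels[sp$train]), 30)
  expect_equal(sum(labels[sp$test]), 30)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), names(labels))
  expect_identical(stratified_split(labels, 0.5, rng_seed = 3), sp)
  # odd class sizes: ceiling rule per class
  odd <- setNames(c(rep(1, 7), rep(0, 8)), make_ids(15))
  so <- stratified_split(odd, 0.5, rng_seed = 1)
  expect_equal(sum(odd[so$train]), 4)      # ceiling(3.5)
  expect_length(so$train, 8)               # ceiling of both halves
  expect_error(stratified_split(setNames(c(1, 0, 0), c("a", "b", "c"))),
               "single member")
})

test_that("confusion metrics match hand computation", {
  perfect <- compute_metrics(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(perfect$ACC, 1)
  expect_equal(perfect$bACC, 1)
  expect_equal(perfect$MCC, 1)
  # all-positive predictor under 30/70 imbalance
  allpos <- compute_metrics(c(rep(1, 3), rep(0, 7)), rep(1, 10))
  expect_equal(allpos$bACC, 0.5)
  expect_equal(allpos$MCC, 0)
  # TP=3 FP=1 FN=2 TN=4
  y <- c(rep(1, 5), rep(0, 5))
  p <- c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0)
  r <- compute_metrics(y, p)
  expect_equal(c(r$TP, r$FP, r$FN, r$TN), c(3, 1, 2, 4))
  expect_equal(r$ACC, 0.7)
  expect_equal(r$bACC, 0.7)
  expect_equal(r$MCC, 0.4082, tolerance = 1e-3)
  expect_error(compute_metrics(integer(0), integer(0)), "empty")
})

test_that("ten-times-five-fold cross-validation fits exactly 50 models", {
  set.seed(2)
  x <- matrix(rnorm(60), 30, 2, dimnames = list(make_ids(30), c("f1", "f2")))
  labels <- setNames(rep(c(0, 1), 15), rownames(x))
  cv <- crossvalidate(x, labels, "lda", repeats = 10, folds = 5, rng_seed = 4)
  expect_equal(nrow(cv$per_fold), 50)
  expect_equal(sort(unique(cv$per_fold$rep)), 1:10)
  expect_equal(sort(unique(cv$per_fold$fold)), 1:5)
})

test_that("a perfectly separable feature scores a perfect CV estimate", {
  labels <- setNames(rep(c(0, 1), each = 20), make_ids(40))
  x <- matrix(ifelse(labels == 1, 5, -5) + rnorm(40, sd = 0.01), 40, 1,
              dimnames = list(names(labels), "f1"))
  cv <- crossvalidate(x, labels, "lda", repeats = 2, folds = 5, rng_seed = 5)
  expect_equal(cv$cv_mean_bACC, 1.0)
})

test_that("null features estimate chance-level balanced accuracy", {
  means <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 500
    x <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(sprintf("P%04d", 1:n), paste0("f", 1:4)))
    labels <- setNames(rbinom(n, 1, 0.5), rownames(x))
    crossvalidate(x, labels, "lda", repeats = 2, folds = 5,
                  rng_seed = s)$cv_mean_bACC
  }, numeric(1))
  expect_true(all(abs(means - 0.5) < 0.05))
})

test_that("training and scaling never see test rows", {
  set.seed(6)
  labels <- setNames(rep(c(0, 1), each = 20), make_ids(40))
  x <- matrix(rnorm(40 * 3), 40, 3,
              dimnames = list(names(labels), paste0("f", 1:3)))
  sp <- stratified_split(labels, 0.5, rng_seed = 7)
  r1 <- train_predict(x, labels, sp, "lda", rng_seed = 8)
  x2 <- x
  probe <- sp$test[1]
  others <- setdiff(sp$test, probe)
  x2[others, ] <- x2[others, ] * 50 + 3   # corrupt all other test rows
  r2 <- train_predict(x2, labels, sp, "lda", rng_seed = 8)
  expect_equal(r1$scores[probe], r2$scores[probe], tolerance = 1e-12)
})

test_that("constant features fall back to a chance-level prior", {
  labels <- setNames(rep(c(0, 1), each = 15), make_ids(30))
  x <- matrix(1, 30, 4, dimnames = list(names(labels), paste0("f", 1:4)))
  sp <- stratified_split(labels, 0.5, rng_seed = 9)
  r <- train_predict(x, labels, sp, "lda", rng_seed = 10)
  expect_equal(r$report$bACC, 0.5)
  expect_lt(diff(range(r$scores)), 1e-8)
})

test_that("deliberate train-on-test leakage is visible as perfect accuracy", {
  labels <- setNames(rep(c(0, 1), each = 10), make_ids(20))
  x <- matrix(ifelse(labels == 1, 3, -3), 20, 1,
              dimnames = list(names(labels), "f1"))
  leaky <- structure(list(train = names(labels), test = names(labels),
                          stratified = FALSE, rng_seed = 1L),
                     class = "split_spec")
  r <- train_predict(x, labels, leaky, "lda", rng_seed = 2)
  expect_equal(r$report$ACC, 1)
})

test_that("optimized SVM parameters come from the grid and match a full scan", {
  set.seed(11)
  n <- 40
  labels <- setNames(rep(c(0, 1), each = n / 2), make_ids(n))
  x <- matrix(rnorm(n * 2), n, 2, dimnames = list(names(labels), c("f1", "f2")))
  x[labels == 1, 1] <- x[labels == 1, 1] + 1.5
  sp <- stratified_split(labels, 0.5, rng_seed = 12)
  fit <- train_predict(x, labels, sp, "svm", optimize = TRUE, rng_seed = 13)
  grid <- 2^(2 * c(-4, -2, -1, 0, 1, 2, 4))
  expect_true(fit$params$cost %in% grid)
  expect_true(fit$params$gamma %in% grid)
  # oracle: exhaustive scan with the same internal CV seed and tie rule
  seed <- derive_seed(derive_seed(13, "gridsearch"), "grid")
  best <- NULL
  for (cost in grid) for (gamma in grid) {
    b <- crossvalidate(x[sp$train, , drop = FALSE], labels[sp$train], "svm",
                       repeats = 1, folds = 5, cost = cost, gamma = gamma,
                       rng_seed = seed)$cv_mean_bACC
    if (is.null(best) || b > best$bACC + 1e-12)
      best <- list(cost = cost, gamma = gamma, bACC = b)
  }
  expect_equal(fit$params$cost, best$cost)
  expect_equal(fit$params$gamma, best$gamma)
})

test_that("weighted voting follows the normalization and tie rules", {
  s1 <- setNames(c(1, 0.2, 0.8), c("a", "b", "c"))
  v1 <- weighted_vote(list(s1), performances = 0.7)
  expect_equal(v1$consensus, s1)
  expect_equal(sum(v1$weights), 1)
  # two equal models with opposite votes: consensus 0.5 -> positive call
  s2 <- setNames(c(0, 1, 0.4), c("a", "b", "c"))
  v2 <- weighted_vote(list(s1, s2), performances = c(0.8, 0.8))
  expect_equal(unname(v2$consensus["a"]), 0.5)
  expect_equal(unname(v2$predictions["a"]), 1L)
  expect_equal(sum(v2$weights), 1, tolerance = 1e-12)
  # a dominant model controls the consensus
  v3 <- weighted_vote(list(s1, s2), performances = c(1, 1e-9))
  expect_equal(unname(v3$predictions), unname(as.integer(s1 >= 0.5)))
  expect_error(weighted_vote(list(s1, s2), c(0, 0)), "zero")
})

test_that("group comparisons report gains and significance correctly", {
  same <- compare_models(list(a = c(0.7, 0.71, 0.72), b = c(0.7, 0.71, 0.72)))
  expect_equal(same$delta_bACC, 0)
  expect_gt(same$p_value, 0.9)
  gap <- compare_models(list(hi = c(0.9, 0.91, 0.92), lo = c(0.5, 0.51, 0.52)))
  expect_equal(gap$delta_bACC, 0.40, tolerance = 1e-12)
  expect_true(gap$significant)
  expect_lt(gap$p_value, 1e-4)
  # Welch oracle by hand: t = 0.4 / sqrt(2 * var / 3)
  t_hand <- 0.4 / sqrt(2 * var(c(0.9, 0.91, 0.92)) / 3)
  p_hand <- 2 * pt(-abs(t_hand), df = 4)
  expect_equal(gap$p_value, p_hand, tolerance = 1e-10)
  three <- compare_models(list(a = c(0.8, 0.81, 0.82), b = c(0.6, 0.61, 0.59),
                               c = c(0.4, 0.42, 0.41)))
  expect_equal(nrow(three), 3)
  expect_false(is.na(attr(three, "anova_p")))
  degen <- compare_models(list(a = c(0.5, 0.5), b = c(0.5, 0.5)))
  expect_true(is.na(degen$p_value))
  expect_false(degen$significant)
})

test_that("a chance-level model stays near 0.5 on large permuted cohorts", {
  ch <- generate_cohort(cohort_spec(500, c(expr = 30), c(ep = 0.5),
                                    n_signal_features = 5, effect_size = 1.5,
                                    rng_seed = 31))
  labels <- labels_of(ch)
  set.seed(32)
  perm <- setNames(sample(labels), names(labels))
  sp <- stratified_split(perm, 0.5, rng_seed = 33)
  r <- train_predict(ch$omics$expr, perm, sp, "lda", rng_seed = 34)
  expect_true(abs(r$report$bACC - 0.5) <= 0.055)
})
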