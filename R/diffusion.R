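#' Graph diffusion kernel of a PSN
#'
#' Regularized Laplacian kernel `K = (I + L)^-1` (default) or heat kernel
#' `K = exp(-t L)`, with `L = D - W` the weighted graph Laplacian. Both are
#' symmetric positive semi-definite; the regularized form is always
#' invertible.
#'
#' @param psn a [new_psn()] object (non-negative weights).
#' @param kernel `"regularized_laplacian"` or `"heat"`.
#' @param t diffusion time for the heat kernel (positive, default 1).
#' @return symmetric patients x patients kernel matrix.
#' @export
diffusion_kernel <- function(psn, kernel = c("regularized_laplacian", "heat"),
                             t = 1) {
  .assert(inherits(psn, "psn"), "psn must be a psn object")
  kernel <- match.arg(kernel)
  w <- psn$w
  .assert(min(w) >= 0, "weights must be non-negative")
  L <- diag(rowSums(w)) - w
  K <- if (kernel == "regularized_laplacian") {
    solve(diag(nrow(w)) + L)
  } else {
    .assert(is.finite(t) && t > 0, "heat kernel time t must be positive and finite")
    es <- eigen(L, symmetric = TRUE)
    ex <- exp(-t * es$values)
    .assert(all(is.finite(ex)), "heat kernel overflow at t = %g", t)
    es$vectors %*% (ex * t(es$vectors))
  }
  K <- (K + t(K)) / 2
  dimnames(K) <- dimnames(w)
  K
}

#' Diffuse a signal vector through a kernel
#'
#' Linear propagation: returns `K %*% y`. Exposed so seed sets (including
#' empty ones) can be replayed exactly.
#'
#' @param K kernel matrix from [diffusion_kernel()].
#' @param y numeric signal vector aligned with the kernel rows.
#' @return named numeric vector of post-diffusion scores.
#' @export
diffuse_signal <- function(K, y) {
  .assert(length(y) == nrow(K), "signal length must match kernel dimension")
  setNames(as.numeric(K %*% y), rownames(K))
}

#' Random-seed diffusion features of a PSN
#'
#' For each of `n_diffusions` rounds, a random 10% of the nodes (without
#' replacement) receive signal 1 and the rest 0; the full post-diffusion
#' signal `K %*% y` is one feature column. The kernel is computed once and
#' reused. Fully reproducible from the seed.
#'
#' @param psn a [new_psn()] object.
#' @param n_diffusions number of diffusion rounds / features (default 1000).
#' @param seed_fraction fraction of nodes seeded per round (default 0.10);
#'   seed count is `round(seed_fraction * n)` and must be at least 1.
#' @param kernel,t forwarded to [diffusion_kernel()].
#' @param rng_seed integer seed.
#' @return patients x `n_diffusions` matrix, `family` attribute
#'   `"diffusion"`, with attributes `n_seeds` (seeds per round) and `seeds`
#'   (the seed index list, for exact replay).
#' @export
diffusion_features <- function(psn, n_diffusions = 1000, seed_fraction = 0.10,
                               kernel = "regularized_laplacian", t = 1,
                               rng_seed = 1L) {
  .assert(.is_count(n_diffusions), "n_diffusions must be a positive count")
  .assert(seed_fraction > 0 && seed_fraction < 1,
          "seed_fraction must be in (0, 1)")
  n <- length(psn$patient_ids)
  n_seeds <- round(seed_fraction * n)
  .assert(n_seeds >= 1, "cohort too small: %d nodes give 0 seeds at fraction %g",
          n, seed_fraction)
  K <- diffusion_kernel(psn, kernel = kernel, t = t)
  set.seed(as.integer(rng_seed))
  seeds <- lapply(seq_len(n_diffusions), function(i) sample.int(n, n_seeds))
  Y <- matrix(0, n, n_diffusions)
  for (i in seq_len(n_diffusions)) Y[seeds[[i]], i] <- 1
  out <- K %*% Y
  dimnames(out) <- list(psn$patient_ids,
                        sprintf("diff_%04d", seq_len(n_diffusions)))
  attr(out, "family") <- "diffusion"
  attr(out, "n_seeds") <- n_seeds
  attr(out, "seeds") <- seeds
  out
}
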