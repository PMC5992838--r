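#' Biased second-order random walks over a PSN
#'
#' node2vec-style walks: from the current node, the unnormalized probability
#' of stepping to node `x` is `w(cur, x)` times `1/p` if `x` is the previous
#' node (return), `1` if `x` neighbours the previous node (local move), and
#' `1/q` otherwise (outward move). Exactly `walks_per_node` walks of
#' `walk_length` positions start from every node; an isolated node yields a
#' single-position walk. Reproducible from the seed.
#'
#' @param psn a [new_psn()] object (non-negative weights).
#' @param p return parameter (> 0).
#' @param q in-out parameter (> 0).
#' @param walks_per_node walks started per node (default 10).
#' @param walk_length positions per walk (default 80).
#' @param rng_seed integer seed.
#' @return a `walk_corpus`: integer matrix of 1-based node indices
#'   (`0` pads truncated walks) with attributes `ids` (patient ids) and
#'   `params`.
#' @export
biased_random_walks <- function(psn, p, q, walks_per_node = 10,
                                walk_length = 80, rng_seed = 1L) {
  .assert(inherits(psn, "psn"), "psn must be a psn object")
  .assert(p > 0 && q > 0, "p and q must be positive")
  .assert(.is_count(walks_per_node) && .is_count(walk_length),
          "walks_per_node and walk_length must be positive counts")
  walks <- .cpp_node2vec_walks(psn$w, p, q, as.integer(walks_per_node),
                               as.integer(walk_length), as.numeric(rng_seed))
  structure(walks, ids = psn$patient_ids,
            params = list(p = p, q = q, walks_per_node = walks_per_node,
                          walk_length = walk_length, rng_seed = rng_seed),
            class = c("walk_corpus", class(walks)))
}

#' Write a walk corpus in word2vec text format
#'
#' One walk per line, whitespace-delimited patient ids.
#'
#' @param corpus a [biased_random_walks()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_walks <- function(corpus, path) {
  ids <- attr(corpus, "ids")
  lines <- apply(unclass(corpus), 1, function(r) paste(ids[r[r > 0]], collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Train a skip-gram node embedding on a walk corpus
#'
#' Skip-gram with negative sampling (word2vec), single-threaded and
#' deterministic for a given seed. Every node must occur in the corpus.
#'
#' @param corpus a `walk_corpus` from [biased_random_walks()].
#' @param d embedding dimension (default 128).
#' @param window context window half-width (default 10; per-pair windows are
#'   uniformly shrunk as in word2vec).
#' @param rng_seed integer seed.
#' @param epochs training passes over the corpus (default 5).
#' @param negative negative samples per positive pair (default 5).
#' @param alpha initial learning rate (default 0.025, linearly decayed).
#' @return nodes x `d` numeric matrix with patient ids as rownames.
#' @export
train_embedding <- function(corpus, d = 128, window = 10, rng_seed = 1L,
                            epochs = 5, negative = 5, alpha = 0.025) {
  .assert(inherits(corpus, "walk_corpus"), "corpus must come from biased_random_walks")
  .assert(.is_count(d) && .is_count(window), "d and window must be positive counts")
  ids <- attr(corpus, "ids")
  m <- unclass(corpus)
  attr(m, "ids") <- NULL
  attr(m, "params") <- NULL
  present <- tabulate(m[m > 0], nbins = length(ids)) > 0
  .assert(all(present), "node(s) absent from corpus: %s",
          paste(ids[!present], collapse = ", "))
  emb <- .cpp_sgns_train(m, length(ids), as.integer(d), as.integer(window),
                         as.integer(negative), as.integer(epochs), alpha,
                         as.numeric(rng_seed))
  rownames(emb) <- ids
  colnames(emb) <- paste0("dim", seq_len(d))
  emb
}

#' Two-run node2vec features of a PSN
#'
#' Runs the biased-walk embedding twice — a locally exploring run
#' (`p = 1, q = 4`) and an outward exploring run (`p = 4, q = 1`) — and
#' concatenates the two `d`-dimensional embeddings, giving `2 * d` features
#' per node (256 at the default `d = 128`). The first `d` columns are
#' exactly the first run's output.
#'
#' @param psn a [new_psn()] object.
#' @param d dimensions per run (default 128).
#' @param runs list of two `c(p, q)` pairs (defaults `c(1, 4)` then
#'   `c(4, 1)`).
#' @param walks_per_node,walk_length,window,epochs walk and training
#'   parameters (node2vec defaults).
#' @param rng_seed master seed; each run derives its own walk and training
#'   seeds from it.
#' @return patients x `2 * d` matrix, `family` attribute `"embedding"`.
#' @export
node2vec_features <- function(psn, d = 128,
                              runs = list(c(p = 1, q = 4), c(p = 4, q = 1)),
                              walks_per_node = 10, walk_length = 80,
                              window = 10, epochs = 5, rng_seed = 1L) {
  .assert(length(runs) >= 1, "need at least one (p, q) run")
  blocks <- lapply(seq_along(runs), function(r) {
    pq <- runs[[r]]
    corpus <- biased_random_walks(psn, p = pq[[1]], q = pq[[2]],
                                  walks_per_node = walks_per_node,
                                  walk_length = walk_length,
                                  rng_seed = derive_seed(rng_seed, "walks", r))
    emb <- train_embedding(corpus, d = d, window = window,
                           rng_seed = derive_seed(rng_seed, "sgns", r),
                           epochs = epochs)
    colnames(emb) <- sprintf("n2v_r%d_%03d", r, seq_len(d))
    emb
  })
  out <- do.call(cbind, blocks)
  attr(out, "family") <- "embedding"
  out
}
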