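#' Specify a synthetic multi-omics cohort
#'
#' Describes a cohort of patients screened with several omics sources, each a
#' patients x features matrix, together with binary clinical endpoints and a
#' planted class signal: for every (source, endpoint) pair,
#' `n_signal_features` features are shifted by `effect_size` standard
#' deviations in the positive class and share a latent factor inducing a
#' within-block correlation of `block_correlation`. The last source is
#' restricted to a sub-cohort (`small_cohort_fraction`), mimicking a data
#' type assayed for only part of a cohort.
#'
#' @param n_patients number of patients.
#' @param sources named integer vector: feature count per source tag, e.g.
#'   `c(expr = 500, cnv = 200)`. The last source is the restricted one.
#' @param endpoints named numeric vector of prevalences in (0, 1).
#' @param n_signal_features number of signal features planted per
#'   (source, endpoint) pair.
#' @param effect_size positive-class mean shift, in units of `noise_sd`.
#' @param block_correlation target pairwise correlation within a signal block,
#'   in `[0, 1)`.
#' @param noise_sd standard deviation of the feature noise.
#' @param small_cohort_fraction fraction in (0, 1] of patients covered by the
#'   last source.
#' @param bias_small_to_positive if `TRUE`, the restricted sub-cohort is
#'   enriched for positive patients (on the first endpoint) instead of being a
#'   uniform random subset.
#' @param rng_seed integer seed; the cohort is fully reproducible from it.
#' @return a validated `cohort_spec` object.
#' @export
#' @examples
#' spec <- cohort_spec(n_patients = 60, sources = c(expr = 100, cnv = 40),
#'                     endpoints = c(death = 0.3), rng_seed = 7)
cohort_spec <- function(n_patients,
                        sources,
                        endpoints,
                        n_signal_features = 20,
                        effect_size = 1,
                        block_correlation = 0.3,
                        noise_sd = 1,
                        small_cohort_fraction = 1,
                        bias_small_to_positive = FALSE,
                        rng_seed = 1L) {
  .assert(.is_count(n_patients), "invalid n_patients: must be a positive count")
  .assert(length(sources) >= 1 && !is.null(names(sources)) && all(nzchar(names(sources))),
          "invalid sources: must be a named vector of feature counts")
  .assert(all(vapply(sources, .is_count, logical(1))),
          "invalid sources: feature counts must be positive counts")
  .assert(length(endpoints) >= 1 && !is.null(names(endpoints)),
          "invalid endpoints: must be a named vector of prevalences")
  .assert(all(endpoints > 0 & endpoints < 1),
          "invalid endpoints: prevalence must be strictly in (0, 1)")
  .assert(.is_count(n_signal_features) || n_signal_features == 0,
          "invalid n_signal_features: must be a non-negative count")
  .assert(all(n_signal_features * length(endpoints) <= sources),
          "invalid n_signal_features: signal blocks exceed features of a source")
  .assert(is.numeric(effect_size) && length(effect_size) == 1 && is.finite(effect_size),
          "invalid effect_size")
  .assert(block_correlation >= 0 && block_correlation < 1,
          "invalid block_correlation: must be in [0, 1)")
  .assert(noise_sd > 0, "invalid noise_sd: must be positive")
  .assert(small_cohort_fraction > 0 && small_cohort_fraction <= 1,
          "invalid small_cohort_fraction: must be in (0, 1]")
  .assert(.is_count(abs(rng_seed) + 1), "invalid rng_seed")
  structure(list(n_patients = as.integer(n_patients),
                 sources = vapply(sources, as.integer, integer(1)),
                 endpoints = endpoints,
                 n_signal_features = as.integer(n_signal_features),
                 effect_size = effect_size,
                 block_correlation = block_correlation,
                 noise_sd = noise_sd,
                 small_cohort_fraction = small_cohort_fraction,
                 bias_small_to_positive = isTRUE(bias_small_to_positive),
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort with planted class signal
#'
#' Endpoint labels are Bernoulli draws at the requested prevalence,
#' independently per endpoint. Non-signal features are pure Gaussian noise.
#' Signal features of a (source, endpoint) block are built from a shared
#' per-patient latent factor, `x = sqrt(rho) * z + sqrt(1 - rho) * eps`
#' (exact target correlation `rho` in expectation), then shifted by
#' `effect_size * noise_sd` for positive patients.
#'
#' @param spec a [cohort_spec()].
#' @return a `synthetic_cohort`: list with `omics` (named list of patients x
#'   features matrices), `clinical` (patients x endpoints 0/1 matrix),
#'   `truth` (signal feature ids per `"source:endpoint"`) and `spec`.
#' @export
#' @examples
#' ch <- generate_cohort(cohort_spec(40, c(expr = 50), c(hr = 0.5), rng_seed = 3))
#' dim(ch$omics$expr)
generate_cohort <- function(spec) {
  .assert(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  set.seed(spec$rng_seed)
  n <- spec$n_patients
  pid <- sprintf("P%04d", seq_len(n))

  clinical <- vapply(spec$endpoints, function(prev) rbinom(n, 1L, prev),
                     integer(n))
  clinical <- matrix(clinical, nrow = n,
                     dimnames = list(pid, names(spec$endpoints)))

  rho <- spec$block_correlation
  truth <- list()
  omics <- list()
  for (src in names(spec$sources)) {
    nf <- spec$sources[[src]]
    fid <- sprintf("%s_f%05d", src, seq_len(nf))
    x <- matrix(rnorm(n * nf, sd = spec$noise_sd), n, nf,
                dimnames = list(pid, fid))
    free <- seq_len(nf)
    for (ep in names(spec$endpoints)) {
      if (spec$n_signal_features == 0) next
      idx <- free[seq_len(spec$n_signal_features)]
      free <- setdiff(free, idx)
      z <- rnorm(n)                      # shared latent, one per patient
      eps <- matrix(rnorm(n * length(idx)), n, length(idx))
      x[, idx] <- spec$noise_sd * (sqrt(rho) * z + sqrt(1 - rho) * eps) +
        spec$effect_size * spec$noise_sd * clinical[, ep]
      truth[[paste(src, ep, sep = ":")]] <- fid[idx]
    }
    attr(x, "source_tag") <- src
    omics[[src]] <- x
  }

  if (spec$small_cohort_fraction < 1) {
    k <- round(spec$small_cohort_fraction * n)
    .assert(k >= 1, "small cohort is empty")
    if (spec$bias_small_to_positive) {
      wts <- 1 + 3 * clinical[, 1]       # positives 4x as likely to be sampled
      keep <- sample(pid, k, prob = wts / sum(wts))
    } else {
      keep <- sample(pid, k)
    }
    last <- names(spec$sources)[length(spec$sources)]
    tag <- attr(omics[[last]], "source_tag")
    omics[[last]] <- omics[[last]][sort(keep), , drop = FALSE]
    attr(omics[[last]], "source_tag") <- tag
  }

  structure(list(omics = omics, clinical = clinical, truth = truth, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d patients, %d source(s), %d endpoint(s)\n",
              x$spec$n_patients, length(x$omics), ncol(x$clinical)))
  for (src in names(x$omics))
    cat(sprintf("  %s: %d x %d\n", src, nrow(x$omics[[src]]), ncol(x$omics[[src]])))
  invisible(x)
}

#' Generate a single-source cohort with correlated patient blocks
#'
#' Patients are partitioned into `n_blocks` groups; two patients of the same
#' group have expected profile correlation `rho` (shared per-block latent
#' feature profile), patients of different groups are uncorrelated. This is
#' the modular structure used to exercise soft-threshold selection and
#' community detection.
#'
#' @param n_patients,n_features matrix dimensions.
#' @param n_blocks number of patient blocks.
#' @param rho within-block profile correlation in `[0, 1)`.
#' @param noise_sd noise standard deviation.
#' @param rng_seed integer seed.
#' @return patients x features matrix with a `block` attribute (integer
#'   block assignment per patient).
#' @export
#' @examples
#' m <- generate_modular_cohort(60, 100, n_blocks = 3, rho = 0.7, rng_seed = 1)
#' table(attr(m, "block"))
generate_modular_cohort <- function(n_patients = 200, n_features = 500,
                                    n_blocks = 4, rho = 0.7, noise_sd = 1,
                                    rng_seed = 1L) {
  .assert(.is_count(n_patients) && .is_count(n_features) && .is_count(n_blocks),
          "invalid dimensions")
  .assert(rho >= 0 && rho < 1, "invalid rho: must be in [0, 1)")
  set.seed(as.integer(rng_seed))
  block <- rep(seq_len(n_blocks), length.out = n_patients)
  z <- matrix(rnorm(n_blocks * n_features), n_blocks, n_features)
  eps <- matrix(rnorm(n_patients * n_features), n_patients, n_features)
  x <- noise_sd * (sqrt(rho) * z[block, , drop = FALSE] + sqrt(1 - rho) * eps)
  dimnames(x) <- list(sprintf("P%04d", seq_len(n_patients)),
                      sprintf("f%05d", seq_len(n_features)))
  attr(x, "block") <- block
  attr(x, "source_tag") <- "modular"
  x
}

#' Write a synthetic cohort to disk
#'
#' Writes one omics TSV per source (features as rows, patients as columns),
#' the clinical table, the planted-truth feature ids (YAML) and a YAML
#' manifest listing all files. Round-trips losslessly through
#' [read_omics_tsv()] / [read_clinical_tsv()].
#'
#' @param cohort a `synthetic_cohort`.
#' @param directory output directory (created if missing).
#' @return the manifest, invisibly (also written as `manifest.yaml`).
#' @export
write_cohort <- function(cohort, directory) {
  .assert(inherits(cohort, "synthetic_cohort"), "cohort must be a synthetic_cohort")
  .assert(ncol(cohort$clinical) >= 1, "invalid cohort: empty endpoint list")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  .assert(dir.exists(directory) && file.access(directory, 2) == 0,
          "directory '%s' is not writable", directory)
  files <- list()
  for (src in names(cohort$omics)) {
    f <- file.path(directory, paste0(src, ".tsv"))
    write_omics_tsv(cohort$omics[[src]], f)
    files$omics[[src]] <- basename(f)
  }
  write_clinical_tsv(cohort$clinical, file.path(directory, "clinical.tsv"))
  files$clinical <- "clinical.tsv"
  yaml::write_yaml(cohort$truth, file.path(directory, "truth.yaml"))
  files$truth <- "truth.yaml"
  manifest <- list(files = files,
                   n_patients = cohort$spec$n_patients,
                   sources = as.list(cohort$spec$sources),
                   endpoints = as.list(cohort$spec$endpoints),
                   rng_seed = cohort$spec$rng_seed)
  yaml::write_yaml(manifest, file.path(directory, "manifest.yaml"))
  invisible(manifest)
}
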