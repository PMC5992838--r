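#' Extract the four topological feature families from a PSN
#'
#' Convenience wrapper producing the centrality (standardized), modularity,
#' embedding and diffusion feature matrices of one network, each tagged with
#' its `family` attribute. Family sub-seeds are derived from the master
#' seed.
#'
#' @param psn a [new_psn()] object.
#' @param families subset of
#'   `c("centrality", "modularity", "embedding", "diffusion")`.
#' @param d embedding dimensions per run (128 gives 256 embedding columns).
#' @param walks_per_node,walk_length,window,epochs embedding parameters.
#' @param n_diffusions,seed_fraction diffusion parameters.
#' @param k_range,partition_tolerance modularity parameters.
#' @param rng_seed master seed for the stochastic families.
#' @return named list of patients x features matrices.
#' @export
topological_features <- function(psn,
                                 families = c("centrality", "modularity",
                                              "embedding", "diffusion"),
                                 d = 128, walks_per_node = 10, walk_length = 80,
                                 window = 10, epochs = 5,
                                 n_diffusions = 1000, seed_fraction = 0.10,
                                 k_range = 2:10, partition_tolerance = 0.05,
                                 rng_seed = 1L) {
  families <- match.arg(families, several.ok = TRUE)
  out <- list()
  if ("centrality" %in% families)
    out$centrality <- suppressWarnings(standardize_features(compute_centralities(psn)))
  if ("modularity" %in% families) {
    parts <- c(spectral_partitions(psn, k_range, partition_tolerance,
                                   rng_seed = derive_seed(rng_seed, "spectral")),
               sbm_partitions(psn, k_range, partition_tolerance,
                              rng_seed = derive_seed(rng_seed, "sbm")))
    out$modularity <- encode_membership(parts)
  }
  if ("embedding" %in% families)
    out$embedding <- node2vec_features(psn, d = d, walks_per_node = walks_per_node,
                                       walk_length = walk_length, window = window,
                                       epochs = epochs,
                                       rng_seed = derive_seed(rng_seed, "embedding"))
  if ("diffusion" %in% families)
    out$diffusion <- diffusion_features(psn, n_diffusions = n_diffusions,
                                        seed_fraction = seed_fraction,
                                        rng_seed = derive_seed(rng_seed, "diffusion"))
  out
}

#' Build a validated pipeline configuration
#'
#' @param cohort_dir directory holding a cohort written by [write_cohort()]
#'   (ignored when `run_pipeline()` is given a cohort object directly).
#' @param out_dir output directory for the run.
#' @param mode `"classical"` (models on reduced omics, no networks),
#'   `"topological"` (models on per-source network features),
#'   `"integrated"` (weighted vote over classical + topological models) or
#'   `"fused"` (topological features of the SNF-fused network).
#' @param endpoints endpoint names to model (`NULL` = all in the clinical
#'   table).
#' @param reduction reduction strategy (see [reduce_features()]).
#' @param fit_scope `"train_only"` (selection statistics computed on
#'   training patients, then applied to all — the leakage-free default) or
#'   `"all_samples"`.
#' @param algorithm classifier for every model.
#' @param beta_candidates,scale_free_target soft-threshold selection.
#' @param network_tag `"WGCNA"` (beta selection) or `"correl"` (beta = 1).
#' @param fusion_K,fusion_T SNF parameters.
#' @param families,d,n_diffusions,k_range feature-family parameters.
#' @param walks_per_node,walk_length,window,epochs embedding parameters.
#' @param train_fraction,cv_repeats,cv_folds modeling parameters.
#' @param rng_seed master seed; every stage derives its own.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(cohort_dir = NULL, out_dir,
                            mode = c("topological", "classical", "integrated", "fused"),
                            endpoints = NULL,
                            reduction = c("none", "wilcoxon_p", "wilcoxon_top",
                                          "variance_top", "pca_var"),
                            fit_scope = c("train_only", "all_samples"),
                            algorithm = c("lda", "rf", "svm"),
                            beta_candidates = c(2, 4, 6, 8, 10, 12),
                            scale_free_target = 0.90,
                            network_tag = c("WGCNA", "correl"),
                            fusion_K = 10, fusion_T = 50,
                            families = c("centrality", "modularity",
                                         "embedding", "diffusion"),
                            d = 128, n_diffusions = 1000, k_range = 2:10,
                            walks_per_node = 10, walk_length = 80,
                            window = 10, epochs = 5,
                            train_fraction = 0.5, cv_repeats = 10, cv_folds = 5,
                            rng_seed = 1L) {
  cfg <- list(cohort_dir = cohort_dir, out_dir = out_dir,
              mode = match.arg(mode), endpoints = endpoints,
              reduction = match.arg(reduction),
              fit_scope = match.arg(fit_scope),
              algorithm = match.arg(algorithm),
              beta_candidates = beta_candidates,
              scale_free_target = scale_free_target,
              network_tag = match.arg(network_tag),
              fusion_K = fusion_K, fusion_T = fusion_T,
              families = families, d = d, n_diffusions = n_diffusions,
              k_range = k_range, walks_per_node = walks_per_node,
              walk_length = walk_length, window = window, epochs = epochs,
              train_fraction = train_fraction, cv_repeats = cv_repeats,
              cv_folds = cv_folds, rng_seed = as.integer(rng_seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected.
#'
#' @param path YAML file whose keys mirror the [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  .assert(length(bad) == 0, "unknown config key(s): %s", paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

# read a cohort directory written by write_cohort()
.read_cohort_dir <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  omics <- list()
  for (src in names(man$files$omics))
    omics[[src]] <- read_omics_tsv(file.path(dir, man$files$omics[[src]]), src)
  clinical <- read_clinical_tsv(file.path(dir, man$files$clinical))
  list(omics = omics, clinical = clinical)
}

#' Run the full classification pipeline
#'
#' Executes preprocess -> network inference (per source, optionally fused)
#' -> topological feature extraction -> per-endpoint model training with
#' repeated cross-validation -> weighted-voting integration, writing every
#' artifact (networks, features, per-model reports, consensus predictions,
#' comparison report, manifest) under `config$out_dir`. Re-running with the
#' same configuration and master seed reproduces the output tree exactly.
#'
#' @param config a [pipeline_config()].
#' @param cohort optional `synthetic_cohort` or list with `omics` and
#'   `clinical`; when missing, `config$cohort_dir` is read.
#' @return (invisibly) a list of per-endpoint results: per-model reports,
#'   cross-validation estimates, vote consensus and comparison report.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  .assert(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  if (is.null(cohort)) {
    .assert(!is.null(config$cohort_dir) && dir.exists(config$cohort_dir),
            "cohort_dir does not exist")
    cohort <- .read_cohort_dir(config$cohort_dir)
  }
  omics <- cohort$omics
  clinical <- cohort$clinical
  endpoints <- if (is.null(config$endpoints)) colnames(clinical) else config$endpoints
  .assert(all(endpoints %in% colnames(clinical)), "unknown endpoint(s)")
  out_dir <- config$out_dir
  for (sub in c("", "networks", "features", "reports"))
    dir.create(file.path(out_dir, sub), showWarnings = FALSE, recursive = TRUE)
  seed <- config$rng_seed
  cohorts <- align_cohorts(omics, clinical)
  ids <- if (length(omics) > 1 && config$mode == "fused") cohorts$small else cohorts$large
  .assert(length(ids) >= 10, "fewer than 10 usable patients")
  results <- list()

  for (ep in endpoints) {
    labels <- setNames(clinical[ids, ep], ids)
    split <- stratified_split(labels, config$train_fraction,
                              derive_seed(seed, "split", ep))
    models <- list()          # name -> list(scores, report, cv)
    networks <- list()

    reduced <- lapply(names(omics), function(src) {
      m <- omics[[src]]
      m <- drop_missing_features(m[intersect(ids, rownames(m)), , drop = FALSE])
      reduce_features(m, config$reduction, labels = labels[rownames(m)],
                      train_ids = if (config$fit_scope == "train_only")
                        intersect(split$train, rownames(m)) else NULL)
    })
    names(reduced) <- names(omics)

    add_model <- function(name, feats) {
      feats <- feats[intersect(ids, rownames(feats)), , drop = FALSE]
      keep <- intersect(rownames(feats), c(split$train, split$test))
      sub_split <- structure(list(train = intersect(split$train, keep),
                                  test = intersect(split$test, keep),
                                  stratified = TRUE, rng_seed = split$rng_seed),
                             class = "split_spec")
      cv <- crossvalidate(feats[sub_split$train, , drop = FALSE],
                          labels[sub_split$train],
                          config$algorithm, repeats = config$cv_repeats,
                          folds = config$cv_folds,
                          rng_seed = derive_seed(seed, "cv", ep, name))
      tp <- train_predict(feats, labels, sub_split, config$algorithm,
                          rng_seed = derive_seed(seed, "fit", ep, name))
      models[[name]] <<- c(tp, list(cv = cv))
    }

    if (config$mode %in% c("classical", "integrated")) {
      for (src in names(reduced)) add_model(paste0("classical_", src), reduced[[src]])
    }
    if (config$mode %in% c("topological", "integrated", "fused")) {
      psns <- lapply(names(reduced), function(src) {
        cm <- pearson_psn(reduced[[src]])
        if (config$network_tag == "correl")
          rescale_correlations(cm, 1, source_tag = src)
        else
          suppressWarnings(select_beta(cm, config$beta_candidates,
                                       config$scale_free_target,
                                       source_tag = src)$psn)
      })
      names(psns) <- names(reduced)
      if (config$mode == "fused" && length(psns) >= 2) {
        common <- Reduce(intersect, lapply(psns, function(p) p$patient_ids))
        psns <- list(fused = fuse_networks(lapply(psns, function(p) {
          p$w <- p$w[common, common]
          p$patient_ids <- common
          p
        }), K = min(config$fusion_K, length(common) - 1), T = config$fusion_T))
      }
      networks <- psns
      for (src in names(psns)) {
        feats <- topological_features(psns[[src]], config$families,
                                      d = config$d,
                                      walks_per_node = config$walks_per_node,
                                      walk_length = config$walk_length,
                                      window = config$window,
                                      epochs = config$epochs,
                                      n_diffusions = config$n_diffusions,
                                      k_range = config$k_range,
                                      rng_seed = derive_seed(seed, "features", src))
        for (fam in names(feats)) {
          write_features_tsv(feats[[fam]],
                             file.path(out_dir, "features",
                                       sprintf("%s_%s_%s.tsv", ep, src, fam)))
          add_model(paste(src, fam, sep = "_"), feats[[fam]])
        }
      }
    }

    # weighted-voting integration: weights from the leakage-free CV estimate
    vote <- NULL
    if (length(models) >= 2) {
      common_te <- Reduce(intersect, lapply(models, function(m) names(m$scores)))
      vote <- weighted_vote(lapply(models, function(m) m$scores[common_te]),
                            vapply(models, function(m) m$cv$cv_mean_bACC, numeric(1)))
      vote$report <- compute_metrics(labels[common_te], vote$predictions)
    }

    report <- do.call(rbind, lapply(names(models), function(nm) {
      m <- models[[nm]]
      data.frame(model = nm, algorithm = m$algorithm,
                 cv_mean_bACC = m$cv$cv_mean_bACC,
                 ACC = m$report$ACC, bACC = m$report$bACC, MCC = m$report$MCC,
                 TP = m$report$TP, FP = m$report$FP, FN = m$report$FN,
                 TN = m$report$TN, stringsAsFactors = FALSE)
    }))
    if (!is.null(vote))
      report <- rbind(report,
                      data.frame(model = "weighted_vote", algorithm = "vote",
                                 cv_mean_bACC = NA,
                                 ACC = vote$report$ACC, bACC = vote$report$bACC,
                                 MCC = vote$report$MCC, TP = vote$report$TP,
                                 FP = vote$report$FP, FN = vote$report$FN,
                                 TN = vote$report$TN, stringsAsFactors = FALSE))
    write.table(report, file.path(out_dir, "reports", paste0(ep, "_models.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(vote)) {
      vdf <- data.frame(patient_id = names(vote$consensus),
                        consensus = vote$consensus,
                        prediction = vote$predictions, stringsAsFactors = FALSE)
      write.table(vdf, file.path(out_dir, "reports", paste0(ep, "_vote.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    comparison <- NULL
    if (length(models) >= 2) {
      groups <- lapply(models, function(m) m$cv$per_fold$bACC)
      comparison <- compare_models(groups)
      write.table(as.data.frame(comparison),
                  file.path(out_dir, "reports", paste0(ep, "_comparison.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    for (src in names(networks))
      write_psn_edgelist(networks[[src]],
                         file.path(out_dir, "networks",
                                   sprintf("%s_%s.tsv", ep, src)))
    results[[ep]] <- list(models = models, vote = vote, report = report,
                          comparison = comparison, split = split)
  }

  manifest <- list(config = unclass(config),
                   config_hash = .config_hash(unclass(config)),
                   endpoints = endpoints,
                   n_patients = length(ids))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(results)
}
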