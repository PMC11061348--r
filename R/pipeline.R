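#' @title Configuration-driven end-to-end pipeline
#' @description `make_synthetic()` materializes a synthetic study (universe,
#'   tested set, assay AUC table, model spec, full-model reference) as the
#'   five interchange files plus ground truth; `run_pipeline()` executes
#'   load -> cluster -> KNN map -> score -> concordance -> triage ->
#'   prioritization over an input directory and writes the seven result
#'   tables plus a run log; `report_run()` prints the cluster-prevalence
#'   partition and false-positive category counts as text tables.
#' @name cli_pipeline
NULL

#' Pipeline configuration
#'
#' @param seed required integer seed driving every stochastic step.
#' @param linkage_variant Ward dialect, `"ward_d2"` (default) or `"ward_d"`.
#' @param cut_height dendrogram cut height (default 1).
#' @param k_candidates candidate KNN neighbourhood sizes (default 1..5).
#' @param split_fraction training fraction for k selection (default 0.8).
#' @param activity_threshold AUC activity threshold (default 0.1).
#' @param tp_quantile true-positive score quantile for triage (default 0.25).
#' @param min_active_assays active-assay floor for triage/prioritization
#'   (default 3).
#' @param normalize_weights normalize subset-model weights (default TRUE).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, linkage_variant = "ward_d2", cut_height = 1,
                            k_candidates = 1:5, split_fraction = 0.8,
                            activity_threshold = 0.1, tp_quantile = 0.25,
                            min_active_assays = 3, normalize_weights = TRUE) {
  if (missing(seed) || is.null(seed)) stop("pipeline config requires `seed`", call. = FALSE)
  assert_scalar_number(seed, "seed")
  structure(list(seed = as.integer(seed), linkage_variant = linkage_variant,
                 cut_height = cut_height, k_candidates = as.integer(k_candidates),
                 split_fraction = split_fraction,
                 activity_threshold = activity_threshold,
                 tp_quantile = tp_quantile,
                 min_active_assays = as.integer(min_active_assays),
                 normalize_weights = isTRUE(normalize_weights)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys match the arguments of [pipeline_config()]; `seed` is
#' required (no hidden default).
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("pipeline config requires `seed`", call. = FALSE)
  pipeline_config(seed = y$seed,
                  linkage_variant = y$linkage_variant %||% "ward_d2",
                  cut_height = y$cut_height %||% 1,
                  k_candidates = unlist(y$k_candidates %||% 1:5),
                  split_fraction = y$split_fraction %||% 0.8,
                  activity_threshold = y$activity_threshold %||% 0.1,
                  tp_quantile = y$tp_quantile %||% 0.25,
                  min_active_assays = y$min_active_assays %||% 3,
                  normalize_weights = y$normalize_weights %||% TRUE)
}

#' Write a synthetic study to an input directory
#'
#' Generates a planted-cluster universe, marks a fraction of it as tested,
#' adds extra tested chemicals drawn from the same cluster masks (the
#' chemicals the KNN mapping must place), generates archetype-driven assay
#' AUCs and a full-model reference for the tested set, and writes
#' `chemicals.csv`, `fingerprints.csv`, `assay_aucs.csv`, `model_spec.yaml`,
#' `full_model.csv`, and `ground_truth.csv`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param uspec a [universe_spec()]; default uses `config$seed`.
#' @param aspec an [archetype_spec()]; default uses `config$seed + 1`.
#' @param tested_fraction fraction of universe chemicals marked tested
#'   (default 0.5).
#' @param n_tested_extra extra non-universe tested chemicals (default one
#'   quarter of the universe size).
#' @return `out_dir`, invisibly; ground truth is also returned as the
#'   attribute `"truth"` (planted cluster labels and archetypes).
#' @export
make_synthetic <- function(config, out_dir,
                           uspec = universe_spec(seed = config$seed),
                           aspec = archetype_spec(seed = config$seed + 1L),
                           tested_fraction = 0.5, n_tested_extra = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  uni <- gen_universe(uspec)
  n_uni <- length(uni$fingerprints$chem_ids)
  n_extra <- n_tested_extra %||% max(1L, floor(n_uni / 4))

  ext <- gen_cluster_members(uni, uspec, n = n_extra, seed = config$seed + 2L)
  tested_in_uni <- with_seed(config$seed + 3L, {
    sort(sample(uni$chemicals$chem_id, floor(n_uni * tested_fraction)))
  })
  uni$chemicals$in_tested_set <- uni$chemicals$chem_id %in% tested_in_uni

  chems <- chemical_table(rbind(as.data.frame(uni$chemicals),
                                as.data.frame(ext$chemicals)))
  fps <- fingerprint_matrix(rbind(uni$fingerprints$bits, ext$fingerprints$bits))
  tested_ids <- chems$chem_id[chems$in_tested_set]

  assay <- gen_assay_table(tested_ids, aspec)
  spec <- model_spec(aspec$assay_names,
                     activity_threshold = config$activity_threshold,
                     normalize_weights = config$normalize_weights)

  write_chemicals(chems, file.path(out_dir, "chemicals.csv"))
  write_fingerprints(fps, file.path(out_dir, "fingerprints.csv"))
  write_assay_aucs(assay$aucs, file.path(out_dir, "assay_aucs.csv"))
  write_model_spec(spec, file.path(out_dir, "model_spec.yaml"))
  write_full_model(assay$ref, file.path(out_dir, "full_model.csv"))

  truth_cl <- c(unclass(uni$truth), unclass(ext$truth))
  truth <- data.frame(chem_id = names(truth_cl),
                      true_cluster = unname(truth_cl))
  truth$archetype <- unname(assay$archetypes[truth$chem_id])
  truth$archetype[is.na(truth$archetype)] <- ""
  utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"), row.names = FALSE)

  invisible(structure(out_dir, truth = list(clusters = truth_cl,
                                            archetypes = assay$archetypes)))
}

#' Run the full analysis pipeline over an input directory
#'
#' Stages: load and join the inputs, cluster the universe fingerprints
#' (Tanimoto + Ward cut), select k and map all tested chemicals into the
#' universe clusters by KNN, score the subset model against the full-model
#' reference, compute per-cluster concordance and the prevalence partition,
#' triage false positives, and build the prioritization list. Each stage
#' halts with its name on error. Writes `clusters.csv`, `kselect.csv`,
#' `predictions.csv`, `cluster_stats.csv`, `partition.csv`, `triage.csv`,
#' `priority.csv`, and `run_log.txt`.
#'
#' @param config a [pipeline_config()].
#' @param inputs_dir directory holding the five interchange files.
#' @param out_dir results directory (created if needed).
#' @return Invisibly, a list with every intermediate object (`bundle`,
#'   `universe_clusters`, `kselect`, `tested_clusters`, `preds`, `stats`,
#'   `partition`, `discrepancy`, `triage`, `priority`).
#' @export
run_pipeline <- function(config, inputs_dir, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("erconcord %s", as.character(utils::packageVersion("erconcord"))),
                 sprintf("seed: %d", config$seed),
                 sprintf("linkage_variant: %s", config$linkage_variant),
                 sprintf("cut_height: %g", config$cut_height),
                 sprintf("k_candidates: %s", paste(config$k_candidates, collapse = ",")),
                 sprintf("split_fraction: %g", config$split_fraction),
                 sprintf("activity_threshold: %g", config$activity_threshold),
                 sprintf("tp_quantile: %g", config$tp_quantile),
                 sprintf("min_active_assays: %d", config$min_active_assays))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  bundle <- stage("load", {
    join_datasets(load_chemicals(file.path(inputs_dir, "chemicals.csv")),
                  load_fingerprints(file.path(inputs_dir, "fingerprints.csv")),
                  load_assay_aucs(file.path(inputs_dir, "assay_aucs.csv")),
                  load_full_model(file.path(inputs_dir, "full_model.csv")))
  })
  spec <- stage("load", load_model_spec(file.path(inputs_dir, "model_spec.yaml")))
  spec$activity_threshold <- config$activity_threshold
  spec$normalize_weights <- config$normalize_weights

  uni_fps <- stage("cluster", fp_subset(bundle$fingerprints, bundle$universe_ids))
  clusters <- stage("cluster", {
    ward_cut(pairwise_distances(uni_fps), cut_height = config$cut_height,
             linkage_variant = config$linkage_variant)
  })
  profile <- cluster_size_profile(clusters)
  log_lines <- c(log_lines,
                 sprintf("universe: %d chemicals in %d clusters (%d singletons, %d doubletons)",
                         profile$n_chemicals, profile$n_clusters,
                         profile$n_singletons, profile$n_doubletons))

  ksel <- stage("knn", {
    select_k(uni_fps, clusters, k_candidates = config$k_candidates,
             split_fraction = config$split_fraction, seed = config$seed)
  })
  tested_fps <- stage("knn", fp_subset(bundle$fingerprints, bundle$tested_ids))
  tested_clusters <- stage("knn", knn_assign(uni_fps, clusters, tested_fps,
                                             k = ksel$chosen_k))
  cov <- cluster_coverage(clusters, tested_clusters)
  log_lines <- c(log_lines,
                 sprintf("knn: chosen k = %d; tested set covers %d of %d clusters",
                         ksel$chosen_k, cov$n_covered_clusters, cov$n_universe_clusters))

  preds <- stage("score", {
    score_predictions(bundle$aucs, spec, bundle$ref, chem_ids = bundle$tested_ids)
  })
  stats <- stage("concordance", cluster_confusion(preds, tested_clusters))
  partition <- stage("concordance", partition_by_prevalence(stats))
  discrepancy <- stage("concordance", global_discrepancy_table(preds))
  tcfg <- triage_config(tp_quantile = config$tp_quantile,
                        min_active_assays = config$min_active_assays,
                        activity_threshold = config$activity_threshold)
  triage <- stage("triage", triage_false_positives(preds, tcfg))
  priority <- stage("prioritize", prioritization_list(preds, tested_clusters, tcfg))

  log_lines <- c(log_lines,
                 sprintf("confusion: TP %d FP %d TN %d FN %d",
                         discrepancy$counts[["TP"]], discrepancy$counts[["FP"]],
                         discrepancy$counts[["TN"]], discrepancy$counts[["FN"]]),
                 sprintf("triage: %s",
                         paste(sprintf("%s=%d", names(triage$counts), triage$counts),
                               collapse = " ")))

  # exports
  utils::write.csv(data.frame(chem_id = names(clusters),
                              cluster_id = unname(unclass(clusters)),
                              set = "universe"),
                   file.path(out_dir, "clusters.csv"), row.names = FALSE)
  utils::write.csv(data.frame(k = names(ksel$accuracy_by_k),
                              accuracy = unname(ksel$accuracy_by_k),
                              chosen = as.integer(names(ksel$accuracy_by_k)) == ksel$chosen_k),
                   file.path(out_dir, "kselect.csv"), row.names = FALSE)
  pred_out <- as.data.frame(preds)
  pred_out$cluster_id <- unname(unclass(tested_clusters)[pred_out$chem_id])
  utils::write.csv(pred_out, file.path(out_dir, "predictions.csv"), row.names = FALSE)
  utils::write.csv(stats$stats, file.path(out_dir, "cluster_stats.csv"), row.names = FALSE)
  utils::write.csv(partition, file.path(out_dir, "partition.csv"), row.names = FALSE)
  utils::write.csv(triage$table, file.path(out_dir, "triage.csv"), row.names = FALSE)
  utils::write.csv(priority$ranked, file.path(out_dir, "priority.csv"), row.names = FALSE)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(bundle = bundle, universe_clusters = clusters, profile = profile,
                 kselect = ksel, tested_clusters = tested_clusters, coverage = cov,
                 preds = preds, stats = stats, partition = partition,
                 discrepancy = discrepancy, triage = triage, priority = priority))
}

#' Print text-table summaries of a pipeline run
#'
#' Prints the cluster-prevalence partition (how many scored clusters are
#' all-negative, mixed, or all-positive under the reference, and how many of
#' the all-negative clusters contain subset-model false positives) and the
#' false-positive triage category counts.
#'
#' @param results_dir directory written by [run_pipeline()].
#' @return Invisibly, a list with both tables.
#' @export
report_run <- function(results_dir) {
  partition <- utils::read.csv(file.path(results_dir, "partition.csv"))
  triage <- utils::read.csv(file.path(results_dir, "triage.csv"))
  stats <- utils::read.csv(file.path(results_dir, "cluster_stats.csv"))

  cat("Cluster partition by full-model prevalence\n")
  cat(sprintf("  %-24s %9s %11s\n", "group", "clusters", "chemicals"))
  for (i in seq_len(nrow(partition))) {
    cat(sprintf("  %-24s %9d %11d\n", partition$group[i],
                partition$n_clusters[i], partition$n_chemicals[i]))
  }
  cat("\nFalse-positive triage categories\n")
  counts <- table(factor(triage$category, levels = TRIAGE_CATEGORIES))
  for (nm in names(counts)) cat(sprintf("  %-24s %d\n", nm, counts[[nm]]))
  if (nrow(stats) > 0) {
    acc <- range(stats$accuracy[!is.na(stats$accuracy)])
    ba <- stats$balanced_accuracy[!is.na(stats$balanced_accuracy)]
    cat(sprintf("\nCluster accuracy range: %.0f%% to %.0f%%\n",
                100 * acc[1], 100 * acc[2]))
    if (length(ba) > 0) {
      cat(sprintf("Cluster balanced-accuracy range: %.0f%% to %.0f%% (mean %.1f%%)\n",
                  100 * min(ba), 100 * max(ba), 100 * mean(ba)))
    }
  }
  invisible(list(partition = partition, triage_counts = counts))
}
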