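#!/usr/bin/env Rscript
# Stage 4: score the subset model and evaluate per-cluster concordance.
#
# Subset scores are weighted means of the four assay AUCs (median and 95%
# bound tables), dichotomized at 0.1 alongside the full-model reference.
# Clusters with at least two tested chemicals get a confusion matrix and the
# derived statistics; clusters are then partitioned by full-model prevalence.

source("analysis/00_config.R")

aucs <- load_assay_aucs(file.path(INPUTS_DIR, "assay_aucs.csv"))
spec <- load_model_spec(file.path(INPUTS_DIR, "model_spec.yaml"))
ref <- load_full_model(file.path(INPUTS_DIR, "full_model.csv"))
mapped <- read_assignment(file.path(TABLES_DIR, "tested_clusters.csv"))

preds <- score_predictions(aucs, spec, ref)
g <- global_discrepancy_table(preds)
cat(sprintf("calls: TP %d, FP %d, TN %d, FN %d (%d discrepancies among %d chemicals)\n",
            g$counts[["TP"]], g$counts[["FP"]], g$counts[["TN"]], g$counts[["FN"]],
            g$n_discrepant, nrow(preds)))
cat(sprintf("false-positive median AUC: subset %.3f vs full %.3f\n",
            g$fp_median_subset_auc, g$fp_median_full_auc))
if (nrow(g$false_negatives) > 0) {
  cat("false negatives (borderline subset scores):\n")
  print(g$false_negatives)
}

stats <- cluster_confusion(preds, mapped, min_cluster_n = 2)
print(stats)
part <- partition_by_prevalence(stats)
print(part)

ba <- stats$stats$balanced_accuracy
mixed <- stats$stats$prevalence > 0 & stats$stats$prevalence < 1
cat(sprintf("balanced accuracy over %d mixed clusters: %.1f%% (range %.0f%%-%.0f%%)\n",
            sum(mixed & !is.na(ba)), 100 * mean(ba[mixed], na.rm = TRUE),
            100 * min(ba[mixed], na.rm = TRUE), 100 * max(ba[mixed], na.rm = TRUE)))

pred_out <- as.data.frame(preds)
pred_out$cluster_id <- as.integer(mapped)[match(pred_out$chem_id, names(mapped))]
write.csv(pred_out, file.path(TABLES_DIR, "predictions.csv"), row.names = FALSE)
write.csv(stats$stats, file.path(TABLES_DIR, "cluster_stats.csv"), row.names = FALSE)
write.csv(part, file.path(TABLES_DIR, "partition.csv"), row.names = FALSE)
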