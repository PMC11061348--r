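#!/usr/bin/env Rscript
# Stage 5: triage the false positives and build the prioritization list.
#
# False positives fall through the ordered cascade (antagonist flag, score
# below the true-positive lower quartile, fewer than three active assays,
# residual); subset-positive chemicals are ranked for follow-up testing and
# negatives in positive-containing clusters are surfaced as cluster-rescued
# candidates.

source("analysis/00_config.R")

preds <- read_predictions(file.path(TABLES_DIR, "predictions.csv"))
mapped <- read_assignment(file.path(TABLES_DIR, "tested_clusters.csv"))

tcfg <- triage_config(tp_quantile = CFG$tp_quantile,
                      min_active_assays = CFG$min_active_assays,
                      activity_threshold = CFG$activity_threshold)
tri <- triage_false_positives(preds, tcfg)
print(tri)

fp_rest <- preds[preds$confusion == "FP" & !preds$antagonist_flag, ]
tp <- preds[preds$confusion == "TP", ]
cat(sprintf("assay-count filter would remove %.1f%% of non-antagonist false positives and %.1f%% of true positives\n",
            100 * mean(fp_rest$n_active_assays < tcfg$min_active_assays),
            100 * mean(tp$n_active_assays < tcfg$min_active_assays)))

pri <- prioritization_list(preds, mapped, tcfg)
cat(sprintf("prioritized %d subset-positive chemicals; %d clusters marked positive; %d cluster-rescued negatives\n",
            nrow(pri$ranked), sum(pri$cluster_enrichment$marked), nrow(pri$rescued)))

write.csv(tri$table, file.path(TABLES_DIR, "triage.csv"), row.names = FALSE)
write.csv(pri$ranked, file.path(TABLES_DIR, "priority.csv"), row.names = FALSE)
write.csv(pri$cluster_enrichment, file.path(TABLES_DIR, "cluster_enrichment.csv"),
          row.names = FALSE)
write.csv(pri$rescued, file.path(TABLES_DIR, "cluster_rescued.csv"), row.names = FALSE)
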