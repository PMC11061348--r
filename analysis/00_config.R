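# Shared configuration for the analysis drivers. Sourced by each numbered
# script; everything downstream is deterministic in this seed.

library(erconcord)

SEED <- 2026L
CFG <- pipeline_config(seed = SEED)
USPEC <- universe_spec(n_clusters = 40, cluster_sizes = 15, seed = SEED)
ASPEC <- archetype_spec(seed = SEED + 1L)
N_TESTED_EXTRA <- 150L

INPUTS_DIR <- "results/inputs"
TABLES_DIR <- "results/tables"
dir.create(TABLES_DIR, recursive = TRUE, showWarnings = FALSE)

# Rebuild a cluster assignment from an exported table, keeping labels verbatim
# (the constructor's first-appearance relabelling must not touch mapped labels).
read_assignment <- function(path) {
  df <- utils::read.csv(path)
  a <- cluster_assignment(df$cluster_id, chem_ids = df$chem_id,
                          linkage_variant = "planted")
  a[] <- as.integer(df$cluster_id)
  a
}

read_predictions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(df, class = c("prediction_set", "data.frame"))
}
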