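# In-code fixture builders shared by the test files.

# Fingerprint matrix from a list of on-bit index vectors.
fp_from_bits <- function(on_bits, n_features, chem_ids = NULL) {
  n <- length(on_bits)
  chem_ids <- chem_ids %||% sprintf("C%02d", seq_len(n))
  bits <- matrix(0L, n, n_features)
  for (i in seq_len(n)) bits[i, on_bits[[i]]] <- 1L
  fingerprint_matrix(bits, chem_ids = chem_ids,
                     feature_names = paste0("b", seq_len(n_features)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand-built prediction set for concordance/triage unit tests. Calls and
# confusion labels are derived from the AUCs via the package's own rules.
make_preds <- function(chem_id, full_auc, subset_auc_med,
                       subset_auc_lo = subset_auc_med,
                       subset_auc_hi = subset_auc_med,
                       antagonist_flag = FALSE,
                       n_active_assays = 4L,
                       threshold = 0.1) {
  df <- data.frame(chem_id = chem_id, full_auc = full_auc,
                   subset_auc_med = subset_auc_med,
                   subset_auc_lo = subset_auc_lo, subset_auc_hi = subset_auc_hi,
                   antagonist_flag = rep_len(antagonist_flag, length(chem_id)),
                   n_active_assays = rep_len(as.integer(n_active_assays), length(chem_id)),
                   stringsAsFactors = FALSE)
  df$full_call <- dichotomize(df$full_auc, threshold)
  df$subset_call <- dichotomize(pmin(1, pmax(0, df$subset_auc_med)), threshold)
  df$confusion <- label_confusion(df$full_call, df$subset_call)
  structure(df, class = c("prediction_set", "data.frame"))
}

# Uniform cluster assignment helper for prediction sets.
assign_clusters <- function(chem_ids, cluster_ids) {
  a <- cluster_assignment(cluster_ids, chem_ids = chem_ids,
                          linkage_variant = "planted")
  a[] <- as.integer(cluster_ids)
  a
}

# Random binary fingerprint matrix.
random_fps <- function(n, n_features, seed, p = 0.3) {
  set.seed(seed)
  bits <- matrix(rbinom(n * n_features, 1L, p), n, n_features)
  # avoid degenerate all-zero rows in generic property tests
  empty <- rowSums(bits) == 0
  bits[empty, 1L] <- 1L
  fingerprint_matrix(bits, chem_ids = sprintf("R%03d", seq_len(n)),
                     feature_names = paste0("b", seq_len(n_features)))
}
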