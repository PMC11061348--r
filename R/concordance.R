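#' @title Per-cluster concordance between subset and full model calls
#' @description For each cluster with enough tested chemicals, a 2x2 confusion
#'   matrix of subset-model calls against full-model calls, the usual derived
#'   statistics (sensitivity, specificity, accuracy, balanced accuracy, PPV,
#'   NPV, prevalence), and AUC agreement summaries (mean subset and full AUC,
#'   mean and sd of their difference). Any ratio with a zero denominator is
#'   reported as `NA` — never coerced to 0 or 1 — and `NA` components are
#'   excluded from cross-cluster averages. Balanced accuracy is `NA` whenever
#'   either of its components is undefined.
#' @name concordance
NULL

confusion_metrics <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  list(n = n,
       sensitivity = sens,
       specificity = spec,
       accuracy = ratio(tp + tn, n),
       balanced_accuracy = if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2,
       ppv = ratio(tp, tp + fp),
       npv = ratio(tn, tn + fn),
       prevalence = ratio(tp + fn, n))
}

#' Per-cluster confusion statistics
#'
#' Clusters with fewer than `min_cluster_n` tested chemicals are not scored
#' (cluster statistics on a single chemical are meaningless); their chemicals
#' are listed separately so the global counts remain conserved.
#'
#' @param preds a `prediction_set` from [score_predictions()].
#' @param assign a [cluster_assignment()] covering every predicted chemical.
#' @param min_cluster_n minimum tested chemicals for a cluster to be scored
#'   (default 2).
#' @return Object of class `cluster_stats`: list with `stats` (one row per
#'   scored cluster), `below_floor` (data frame `chem_id`, `cluster_id`,
#'   `confusion`), and `min_cluster_n`.
#' @export
cluster_confusion <- function(preds, assign, min_cluster_n = 2) {
  stopifnot(inherits(preds, "prediction_set"), inherits(assign, "cluster_assignment"))
  unassigned <- setdiff(preds$chem_id, names(assign))
  if (length(unassigned) > 0) {
    stop("predicted chemical(s) without a cluster: ",
         paste(utils::head(unassigned, 5), collapse = ", "), call. = FALSE)
  }
  cl <- unclass(assign)[preds$chem_id]
  sizes <- table(cl)
  scored_ids <- as.integer(names(sizes)[sizes >= min_cluster_n])

  rows <- lapply(scored_ids, function(cid) {
    p <- preds[cl == cid, , drop = FALSE]
    tp <- sum(p$confusion == "TP"); fp <- sum(p$confusion == "FP")
    tn <- sum(p$confusion == "TN"); fn <- sum(p$confusion == "FN")
    m <- confusion_metrics(tp, fp, tn, fn)
    diff <- p$subset_auc_med - p$full_auc
    data.frame(cluster_id = cid, n = m$n, tp = tp, fp = fp, tn = tn, fn = fn,
               sensitivity = m$sensitivity, specificity = m$specificity,
               accuracy = m$accuracy, balanced_accuracy = m$balanced_accuracy,
               ppv = m$ppv, npv = m$npv, prevalence = m$prevalence,
               mean_subset_auc = mean(p$subset_auc_med),
               mean_full_auc = mean(p$full_auc),
               mean_auc_diff = mean(diff),
               sd_auc_diff = if (nrow(p) > 1) stats::sd(diff) else NA_real_)
  })
  stats <- do.call(rbind, rows) %||% data.frame()
  below <- preds$chem_id[!(cl %in% scored_ids)]
  below_floor <- data.frame(chem_id = below,
                            cluster_id = unname(cl[match(below, preds$chem_id)]),
                            confusion = preds$confusion[match(below, preds$chem_id)])
  structure(list(stats = stats, below_floor = below_floor,
                 min_cluster_n = min_cluster_n),
            class = "cluster_stats")
}

#' @export
print.cluster_stats <- function(x, ...) {
  cat(sprintf("<cluster_stats> %d scored clusters (>= %d chemicals), %d chemicals below floor\n",
              nrow(x$stats), x$min_cluster_n, nrow(x$below_floor)))
  if (nrow(x$stats) > 0) {
    ba <- x$stats$balanced_accuracy
    cat(sprintf("  mean balanced accuracy over %d defined clusters: %.3f\n",
                sum(!is.na(ba)), mean(ba, na.rm = TRUE)))
  }
  invisible(x)
}

#' Partition scored clusters by full-model prevalence
#'
#' Splits scored clusters into prevalence = 0 (no full-model active chemical),
#' mixed (0 < prevalence < 1), and prevalence = 1 groups, with the
#' prevalence-0 group further divided into perfect-match clusters (no false
#' positives) and clusters containing at least one false positive.
#'
#' @param stats a `cluster_stats` object from [cluster_confusion()].
#' @return Data frame with columns `group`, `n_clusters`, `n_chemicals`,
#'   plus attribute `fp_chemicals_in_prev0` (false-positive count inside the
#'   prevalence-0 group).
#' @export
partition_by_prevalence <- function(stats) {
  stopifnot(inherits(stats, "cluster_stats"))
  s <- stats$stats
  grp <- function(keep) c(n_clusters = sum(keep), n_chemicals = sum(s$n[keep]))
  prev0 <- s$prevalence == 0
  out <- rbind(
    data.frame(group = "prevalence_0", t(grp(prev0))),
    data.frame(group = "prevalence_0_perfect", t(grp(prev0 & s$fp == 0))),
    data.frame(group = "prevalence_0_with_fp", t(grp(prev0 & s$fp > 0))),
    data.frame(group = "mixed", t(grp(s$prevalence > 0 & s$prevalence < 1))),
    data.frame(group = "prevalence_1", t(grp(s$prevalence == 1)))
  )
  rownames(out) <- NULL
  attr(out, "fp_chemicals_in_prev0") <- sum(s$fp[prev0])
  out
}

#' Global discrepancy summary
#'
#' Overall confusion counts, the median subset and full AUC among
#' false-positive chemicals, and the full list of false negatives with both
#' scores (false negatives are the costly error for an early screen, so each
#' is surfaced individually).
#'
#' @param preds a `prediction_set`.
#' @return List with `counts` (named TP/FP/TN/FN), `n_discrepant`,
#'   `fp_median_subset_auc`, `fp_median_full_auc`, and `false_negatives`
#'   (data frame `chem_id`, `subset_auc_med`, `full_auc`).
#' @export
global_discrepancy_table <- function(preds) {
  stopifnot(inherits(preds, "prediction_set"))
  counts <- vapply(c("TP", "FP", "TN", "FN"),
                   function(lab) sum(preds$confusion == lab), integer(1))
  fps <- preds[preds$confusion == "FP", , drop = FALSE]
  fns <- preds[preds$confusion == "FN", , drop = FALSE]
  list(counts = counts,
       n_discrepant = counts[["FP"]] + counts[["FN"]],
       fp_median_subset_auc = if (nrow(fps) > 0) stats::median(fps$subset_auc_med) else NA_real_,
       fp_median_full_auc = if (nrow(fps) > 0) stats::median(fps$full_auc) else NA_real_,
       false_negatives = data.frame(chem_id = fns$chem_id,
                                    subset_auc_med = fns$subset_auc_med,
                                    full_auc = fns$full_auc))
}
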