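#' @title False-positive triage and screening prioritization
#' @description Chemicals called active by the subset model but inactive by
#'   the full reference are triaged through an ordered rule cascade, each
#'   false positive landing in the first matching category:
#'   1. `antagonist_flagged` — the pathway model marks the chemical as an
#'      antagonist; a follow-up antagonist assay battery would catch it, and
#'      for prioritization any estrogen activity is of interest anyway.
#'   2. `below_tp_quartile` — subset score strictly below the lower quartile
#'      of the true-positive score distribution; such chemicals would be
#'      tested after 75% of the true positives under score-ranked screening.
#'   3. `low_assay_count` — active in fewer than the required number of the
#'      model's assays (default 3 of 4); compensates for the loss of the
#'      full model's interference ("pseudoreceptor") channels.
#'   4. `residual_high_priority` — survives all filters; a genuine candidate
#'      for follow-up testing.
#'   The cascade reproduces successive set subtraction on the false-positive
#'   pool, so per-category counts sum to the number of false positives.
#' @name triage
NULL

TRIAGE_CATEGORIES <- c("antagonist_flagged", "below_tp_quartile",
                       "low_assay_count", "residual_high_priority")

#' Triage configuration
#'
#' @param tp_quantile quantile of the true-positive subset score used as the
#'   low-score cut (default 0.25, the lower quartile).
#' @param min_active_assays minimum active assays for a positive to be kept
#'   (default 3).
#' @param activity_threshold AUC activity threshold (default 0.1), used for
#'   confidence-interval overlap flagging.
#' @param quantile_type quantile algorithm passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @return Object of class `triage_config`.
#' @export
triage_config <- function(tp_quantile = 0.25, min_active_assays = 3,
                          activity_threshold = 0.1, quantile_type = 7) {
  assert_scalar_number(tp_quantile, "tp_quantile")
  if (tp_quantile <= 0 || tp_quantile >= 1) {
    stop("tp_quantile must be strictly between 0 and 1", call. = FALSE)
  }
  assert_scalar_number(min_active_assays, "min_active_assays")
  if (min_active_assays < 1) stop("min_active_assays must be >= 1", call. = FALSE)
  assert_scalar_number(activity_threshold, "activity_threshold")
  structure(list(tp_quantile = tp_quantile,
                 min_active_assays = as.integer(min_active_assays),
                 activity_threshold = activity_threshold,
                 quantile_type = quantile_type),
            class = "triage_config")
}

#' Quantile of the true-positive subset scores
#'
#' @param preds a `prediction_set` containing at least one true positive.
#' @param q probability (default 0.25).
#' @param quantile_type algorithm for [stats::quantile()] (default 7,
#'   linear interpolation).
#' @return The q-quantile of `subset_auc_med` over true-positive chemicals.
#' @export
tp_auc_quantile <- function(preds, q = 0.25, quantile_type = 7) {
  stopifnot(inherits(preds, "prediction_set"))
  x <- preds$subset_auc_med[preds$confusion == "TP"]
  if (length(x) == 0L) stop("no true-positive chemicals to take a quantile over",
                            call. = FALSE)
  unname(stats::quantile(x, probs = q, type = quantile_type))
}

#' Does a chemical's AUC confidence interval overlap the activity threshold?
#'
#' True when the closed interval `[subset_auc_lo, subset_auc_hi]` contains the
#' threshold, or — when the reference carries confidence bounds — when
#' `[full_auc_lo, full_auc_hi]` does. If the reference has no bounds, only the
#' subset interval is used (reported once via a message).
#'
#' @param preds a `prediction_set` (any subset of rows).
#' @param threshold activity threshold (default 0.1).
#' @return Logical vector, one entry per row of `preds`.
#' @export
ci_overlaps_threshold <- function(preds, threshold = 0.1) {
  assert_scalar_number(threshold, "threshold")
  subset_hit <- preds$subset_auc_lo <= threshold & threshold <= preds$subset_auc_hi
  if (all(c("full_auc_lo", "full_auc_hi") %in% names(preds))) {
    full_hit <- preds$full_auc_lo <= threshold & threshold <= preds$full_auc_hi
    subset_hit | full_hit
  } else {
    message("ci_overlaps_threshold: no full-model confidence bounds; using subset interval only")
    subset_hit
  }
}

#' Triage false-positive chemicals through the rule cascade
#'
#' @param preds a `prediction_set`.
#' @param cfg a [triage_config()].
#' @return Object of class `triage_report`: list with `table` (one row per
#'   false positive: `chem_id`, `category`, `subset_auc_med`,
#'   `n_active_assays`, `antagonist_flag`, `ci_overlaps_threshold`), `counts`
#'   (named by category, summing to the number of false positives),
#'   `tp_quantile_value`, `n_fp`, and `config`.
#' @export
triage_false_positives <- function(preds, cfg = triage_config()) {
  stopifnot(inherits(preds, "prediction_set"), inherits(cfg, "triage_config"))
  cut <- tp_auc_quantile(preds, q = cfg$tp_quantile, quantile_type = cfg$quantile_type)
  fps <- preds[preds$confusion == "FP", , drop = FALSE]

  category <- character(nrow(fps))
  for (i in seq_len(nrow(fps))) {
    category[i] <- if (isTRUE(fps$antagonist_flag[i])) {
      "antagonist_flagged"
    } else if (fps$subset_auc_med[i] < cut) { # strict: an FP exactly at the quartile is kept
      "below_tp_quartile"
    } else if (fps$n_active_assays[i] < cfg$min_active_assays) {
      "low_assay_count"
    } else {
      "residual_high_priority"
    }
  }
  tab <- data.frame(chem_id = fps$chem_id,
                    category = factor(category, levels = TRIAGE_CATEGORIES),
                    subset_auc_med = fps$subset_auc_med,
                    n_active_assays = fps$n_active_assays,
                    antagonist_flag = fps$antagonist_flag,
                    ci_overlaps_threshold =
                      if (nrow(fps) > 0) ci_overlaps_threshold(fps, cfg$activity_threshold)
                      else logical(0))
  rownames(tab) <- NULL
  counts <- table(tab$category)
  structure(list(table = tab,
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 tp_quantile_value = cut,
                 n_fp = nrow(fps),
                 config = cfg),
            class = "triage_report")
}

#' @export
print.triage_report <- function(x, ...) {
  cat(sprintf("<triage_report> %d false positives (TP %.0f%%-quantile score %.4f)\n",
              x$n_fp, 100 * x$config$tp_quantile, x$tp_quantile_value))
  for (nm in names(x$counts)) cat(sprintf("  %-24s %d\n", nm, x$counts[[nm]]))
  invisible(x)
}

#' Ranked prioritization list and cluster enrichment table
#'
#' Subset-model positives are ranked for follow-up testing: chemicals active
#' in at least `min_active_assays` assays come first, then by descending
#' subset score, ties by identifier. Clusters containing at least one
#' subset-positive chemical are marked, with their fraction of positive
#' chemicals; subset-negative chemicals sitting in marked clusters are listed
#' as "cluster-rescued" candidates (structural neighbours of actives whose
#' negative call deserves a second look).
#'
#' @param preds a `prediction_set`.
#' @param assign a [cluster_assignment()] covering the predicted chemicals.
#' @param cfg a [triage_config()].
#' @return List with `ranked` (prioritized positives), `cluster_enrichment`
#'   (per cluster: `n`, `n_positive`, `positive_fraction`, `marked`), and
#'   `rescued` (negative chemicals in marked clusters).
#' @export
prioritization_list <- function(preds, assign, cfg = triage_config()) {
  stopifnot(inherits(preds, "prediction_set"), inherits(assign, "cluster_assignment"))
  unassigned <- setdiff(preds$chem_id, names(assign))
  if (length(unassigned) > 0) {
    stop("predicted chemical(s) without a cluster: ",
         paste(utils::head(unassigned, 5), collapse = ", "), call. = FALSE)
  }
  cl <- unclass(assign)[preds$chem_id]
  pos <- preds[preds$subset_call == 1L, , drop = FALSE]

  if (nrow(pos) > 0) {
    meets <- pos$n_active_assays >= cfg$min_active_assays
    ord <- order(-meets, -pos$subset_auc_med, pos$chem_id)
    ranked <- data.frame(rank = seq_len(nrow(pos)),
                         chem_id = pos$chem_id[ord],
                         cluster_id = unname(cl[match(pos$chem_id[ord], preds$chem_id)]),
                         subset_auc_med = pos$subset_auc_med[ord],
                         n_active_assays = pos$n_active_assays[ord],
                         meets_assay_rule = meets[ord],
                         confusion = pos$confusion[ord])
  } else {
    ranked <- data.frame(rank = integer(0), chem_id = character(0),
                         cluster_id = integer(0), subset_auc_med = numeric(0),
                         n_active_assays = integer(0), meets_assay_rule = logical(0),
                         confusion = character(0))
  }

  cl_ids <- sort(unique(cl))
  enr <- data.frame(cluster_id = cl_ids,
                    n = as.integer(table(factor(cl, levels = cl_ids))),
                    n_positive = vapply(cl_ids, function(cid) {
                      sum(preds$subset_call[cl == cid] == 1L)
                    }, integer(1)))
  enr$positive_fraction <- enr$n_positive / enr$n
  enr$marked <- enr$n_positive > 0
  rownames(enr) <- NULL

  marked_cl <- enr$cluster_id[enr$marked]
  neg <- preds[preds$subset_call == 0L & cl %in% marked_cl, , drop = FALSE]
  rescued <- data.frame(chem_id = neg$chem_id,
                        cluster_id = unname(cl[match(neg$chem_id, preds$chem_id)]),
                        subset_auc_med = neg$subset_auc_med,
                        full_auc = neg$full_auc)
  rownames(rescued) <- NULL
  list(ranked = ranked, cluster_enrichment = enr, rescued = rescued)
}
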