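#' @title Subset-model agonist scores and activity calls
#' @description The reduced-battery agonist score for a chemical is the
#'   weighted mean of its per-assay AUC values over the model's assays,
#'   `sum(w_i * auc_i) / sum(w_i)` (optionally the raw weighted sum), computed
#'   from the median AUC table and, analogously, from the lower and upper 95%
#'   confidence-bound tables. Scores at or above the activity threshold
#'   (default 0.1, closed comparison) are called active. Confusion labels
#'   take the full-model call as truth: TP = active in both, FP = active only
#'   in the subset model, FN = active only in the full model, TN = neither.
#' @name er_models
NULL

#' Weighted subset-model AUC score
#'
#' @param assay_aucs named numeric vector of per-assay AUC values covering all
#'   of the model's assays (no missing values).
#' @param spec a [model_spec()].
#' @return The weighted score; in \[0, 1\] when weights are normalized.
#' @export
#' @examples
#' spec <- model_spec(letters[1:4], weights = c(2, 1, 1, 0))
#' subset_auc(c(a = 0.4, b = 0.1, c = 0.1, d = 0.3), spec) # (0.8+0.1+0.1+0)/4 = 0.25
subset_auc <- function(assay_aucs, spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (!is.null(names(assay_aucs))) {
    miss <- setdiff(spec$assay_names, names(assay_aucs))
    if (length(miss) > 0) {
      stop("missing assay value(s): ", paste(miss, collapse = ", "), call. = FALSE)
    }
    assay_aucs <- assay_aucs[spec$assay_names]
  } else if (length(assay_aucs) != length(spec$assay_names)) {
    stop("expected ", length(spec$assay_names), " assay values, got ",
         length(assay_aucs), call. = FALSE)
  }
  if (anyNA(assay_aucs)) {
    stop("missing assay value(s): ",
         paste(spec$assay_names[is.na(assay_aucs)], collapse = ", "), call. = FALSE)
  }
  w <- unname(spec$weights)
  s <- sum(w * assay_aucs)
  if (spec$normalize_weights) s / sum(w) else s
}

#' Dichotomize a model AUC score into an activity call
#'
#' Closed comparison: a score exactly at the threshold is active. Scores just
#' below (e.g. 0.0976 or 0.0901 against 0.1) are borderline negatives.
#'
#' @param auc numeric vector of scores in \[0, 1\].
#' @param threshold activity threshold (default 0.1).
#' @return Integer vector of 0/1 calls.
#' @export
dichotomize <- function(auc, threshold = 0.1) {
  assert_scalar_number(threshold, "threshold")
  if (any(!is.finite(auc)) || any(auc < 0 | auc > 1)) {
    stop("AUC scores must be finite and in [0, 1]", call. = FALSE)
  }
  as.integer(auc >= threshold)
}

#' Count active assays for a chemical
#'
#' An assay counts as active when its AUC is strictly greater than the floor
#' (default 0), so any non-zero response counts.
#'
#' @param assay_aucs numeric vector of per-assay AUC values in \[0, 1\].
#' @param floor activity floor (default 0, strict-greater rule).
#' @return Integer count.
#' @export
count_active_assays <- function(assay_aucs, floor = 0) {
  assert_scalar_number(floor, "floor")
  if (any(!is.finite(assay_aucs)) || any(assay_aucs < 0 | assay_aucs > 1)) {
    stop("assay AUC values must be finite and in [0, 1]", call. = FALSE)
  }
  sum(assay_aucs > floor)
}

#' Confusion label from a (full, subset) call pair
#'
#' @param full_call,subset_call 0/1 activity calls (vectors of equal length);
#'   the full-model call is the reference.
#' @return Character vector in `{"TP","FP","TN","FN"}`.
#' @export
label_confusion <- function(full_call, subset_call) {
  if (length(full_call) != length(subset_call)) {
    stop("call vectors must have equal length", call. = FALSE)
  }
  if (!all(full_call %in% 0:1) || !all(subset_call %in% 0:1)) {
    stop("calls must be 0 or 1", call. = FALSE)
  }
  c("TN", "FP", "FN", "TP")[1L + as.integer(subset_call) + 2L * as.integer(full_call)]
}

#' Score a tested chemical set under a subset model
#'
#' Computes, per chemical: the subset-model score from the median AUC table
#' and from the lower/upper confidence-bound tables (bound propagation — the
#' score function applied to the bound matrices, not resampling), activity
#' calls for subset and full models, the active-assay count over the model's
#' assays, and the confusion label against the full-model reference.
#'
#' Chemicals missing any of the model's assays in the median table, or absent
#' from the reference, are excluded and listed in the `excluded` attribute —
#' never silently dropped.
#'
#' @param aucs an [assay_auc_table()].
#' @param spec a [model_spec()].
#' @param ref a [full_model_reference()].
#' @param chem_ids optional subset of chemicals to score (default: all in `aucs`).
#' @return A data frame of class `prediction_set` with columns `chem_id`,
#'   `full_auc`, `full_call`, `subset_auc_med`, `subset_auc_lo`,
#'   `subset_auc_hi`, `subset_call`, `antagonist_flag`, `n_active_assays`,
#'   `confusion` (plus `full_auc_lo`/`full_auc_hi` when the reference carries
#'   them), and attribute `excluded` (data frame `chem_id`, `reason`).
#' @export
score_predictions <- function(aucs, spec, ref, chem_ids = NULL) {
  stopifnot(inherits(aucs, "assay_auc_table"), inherits(spec, "model_spec"))
  ref <- full_model_reference(as.data.frame(ref))
  miss_assay <- setdiff(spec$assay_names, aucs$assay_names)
  if (length(miss_assay) > 0) {
    stop("AUC table lacks model assay(s): ", paste(miss_assay, collapse = ", "),
         call. = FALSE)
  }
  ids <- chem_ids %||% aucs$chem_ids
  ids <- as.character(ids)
  unknown <- setdiff(ids, aucs$chem_ids)
  if (length(unknown) > 0) {
    stop("chemicals absent from the AUC table: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }

  med <- aucs$auc_med[ids, spec$assay_names, drop = FALSE]
  lo <- aucs$auc_lo[ids, spec$assay_names, drop = FALSE]
  hi <- aucs$auc_hi[ids, spec$assay_names, drop = FALSE]

  excl <- data.frame(chem_id = character(0), reason = character(0))
  incomplete <- ids[rowSums(is.na(med)) > 0]
  if (length(incomplete) > 0) {
    excl <- rbind(excl, data.frame(chem_id = incomplete, reason = "missing assay AUC"))
  }
  no_ref <- setdiff(ids, ref$chem_id)
  no_ref <- setdiff(no_ref, incomplete)
  if (length(no_ref) > 0) {
    excl <- rbind(excl, data.frame(chem_id = no_ref, reason = "no full-model reference"))
  }
  keep <- setdiff(ids, excl$chem_id)
  if (length(keep) == 0L) stop("no scoreable chemicals", call. = FALSE)
  if (nrow(excl) > 0) {
    message(sprintf("score_predictions: excluded %d chemical(s) (%s)",
                    nrow(excl), paste(unique(excl$reason), collapse = "; ")))
  }

  w <- unname(spec$weights)
  wsum <- if (spec$normalize_weights) sum(w) else 1
  score <- function(m) as.vector(m[keep, , drop = FALSE] %*% w) / wsum

  refrow <- ref[match(keep, ref$chem_id), , drop = FALSE]
  out <- data.frame(
    chem_id = keep,
    full_auc = refrow$full_auc,
    subset_auc_med = score(med),
    subset_auc_lo = score(lo),
    subset_auc_hi = score(hi),
    antagonist_flag = refrow$antagonist_flag,
    stringsAsFactors = FALSE
  )
  out$full_call <- dichotomize(out$full_auc, spec$activity_threshold)
  out$subset_call <- dichotomize(clip01(out$subset_auc_med), spec$activity_threshold)
  out$n_active_assays <- apply(med[keep, , drop = FALSE], 1L, count_active_assays,
                               floor = spec$assay_activity_floor)
  out$confusion <- label_confusion(out$full_call, out$subset_call)
  if (all(c("full_auc_lo", "full_auc_hi") %in% names(refrow))) {
    out$full_auc_lo <- refrow$full_auc_lo
    out$full_auc_hi <- refrow$full_auc_hi
  }
  rownames(out) <- NULL
  structure(out, excluded = excl, model_spec = spec,
            class = c("prediction_set", "data.frame"))
}
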