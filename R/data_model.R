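#' @title Typed ingestion of chemical screening tables
#' @description Readers and validating constructors for the five interchange
#'   tables used throughout the pipeline: chemical records, binary structural
#'   fingerprints, chemical-by-assay AUC tables, subset-model specifications,
#'   and full-model reference predictions. All interchange is delimited text
#'   (CSV) plus one YAML model specification; no binary formats are read.
#' @name data_model
NULL

# ---- constructors -----------------------------------------------------------

#' Binary fingerprint matrix
#'
#' Chemical-by-feature matrix of substructure presence bits (ToxPrint-style;
#' the canonical feature library has 729 bits, but any width is accepted).
#'
#' @param bits numeric/integer matrix whose entries are exactly 0 or 1.
#' @param chem_ids character vector of unique chemical identifiers, one per row.
#' @param feature_names character vector of feature labels, one per column.
#' @return An object of class `fingerprint_matrix`: a list with elements
#'   `chem_ids`, `feature_names` and `bits` (integer matrix with dimnames).
#' @export
fingerprint_matrix <- function(bits, chem_ids = rownames(bits),
                               feature_names = colnames(bits)) {
  bits <- as.matrix(bits)
  if (is.null(chem_ids)) stop("fingerprint matrix needs chemical identifiers", call. = FALSE)
  chem_ids <- as.character(chem_ids)
  if (is.null(feature_names)) feature_names <- paste0("bit", seq_len(ncol(bits)))
  feature_names <- as.character(feature_names)
  if (length(chem_ids) != nrow(bits)) {
    stop("length(chem_ids) must equal nrow(bits)", call. = FALSE)
  }
  if (length(feature_names) != ncol(bits)) {
    stop("length(feature_names) must equal ncol(bits)", call. = FALSE)
  }
  if (anyDuplicated(chem_ids)) {
    stop("duplicate chem_ids in fingerprint matrix: ",
         paste(unique(chem_ids[duplicated(chem_ids)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(matrix(!(bits %in% c(0, 1)), nrow = nrow(bits)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("fingerprint value not in {0,1} at row '%s', column '%s'",
                 chem_ids[bad[1, 1]], feature_names[bad[1, 2]]),
         call. = FALSE)
  }
  storage.mode(bits) <- "integer"
  dimnames(bits) <- list(chem_ids, feature_names)
  structure(list(chem_ids = chem_ids, feature_names = feature_names, bits = bits),
            class = "fingerprint_matrix")
}

#' @export
print.fingerprint_matrix <- function(x, ...) {
  cat(sprintf("<fingerprint_matrix> %d chemicals x %d features (%.1f%% bits set)\n",
              nrow(x$bits), ncol(x$bits), 100 * mean(x$bits)))
  invisible(x)
}

#' Subset a fingerprint matrix by chemical identifier
#'
#' @param fps a [fingerprint_matrix()].
#' @param chem_ids identifiers to keep, in the order requested.
#' @return A new `fingerprint_matrix` restricted to `chem_ids`.
#' @export
fp_subset <- function(fps, chem_ids) {
  stopifnot(inherits(fps, "fingerprint_matrix"))
  missing <- setdiff(chem_ids, fps$chem_ids)
  if (length(missing) > 0) {
    stop("chemicals absent from fingerprint matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  fingerprint_matrix(fps$bits[chem_ids, , drop = FALSE], chem_ids, fps$feature_names)
}

#' Cluster assignment
#'
#' Mapping from chemical identifier to a positive integer cluster id, together
#' with the cut height and linkage dialect that produced it. Ids are relabelled
#' 1..K in order of first appearance so the labelling is deterministic for a
#' fixed input order.
#'
#' @param cluster_id integer vector of cluster labels.
#' @param chem_ids character vector of identifiers (or `names(cluster_id)`).
#' @param cut_height dendrogram cut height that produced the labels (`NA` for
#'   planted ground-truth partitions).
#' @param linkage_variant one of `"ward_d2"`, `"ward_d"`, or `"planted"`.
#' @return Object of class `cluster_assignment`: named integer vector of
#'   contiguous labels 1..K with attributes `cut_height` and `linkage_variant`.
#' @export
cluster_assignment <- function(cluster_id, chem_ids = names(cluster_id),
                               cut_height = NA_real_,
                               linkage_variant = c("ward_d2", "ward_d", "planted")) {
  linkage_variant <- match.arg(linkage_variant)
  if (is.null(chem_ids)) stop("cluster assignment needs chemical identifiers", call. = FALSE)
  chem_ids <- as.character(chem_ids)
  if (length(chem_ids) != length(cluster_id)) {
    stop("chem_ids and cluster_id lengths differ", call. = FALSE)
  }
  if (length(cluster_id) == 0L) stop("empty cluster assignment", call. = FALSE)
  if (anyDuplicated(chem_ids)) stop("duplicate chem_ids in cluster assignment", call. = FALSE)
  if (anyNA(cluster_id)) stop("NA cluster labels", call. = FALSE)
  # contiguous relabelling by first appearance
  relab <- match(cluster_id, unique(cluster_id))
  structure(stats::setNames(as.integer(relab), chem_ids),
            cut_height = cut_height, linkage_variant = linkage_variant,
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d chemicals in %d clusters (cut height %s, %s linkage)\n",
              length(x), length(unique(unclass(x))),
              format(attr(x, "cut_height")), attr(x, "linkage_variant")))
  invisible(x)
}

#' Chemical-by-assay AUC table
#'
#' Median and 95% confidence-bound AUC scores per chemical-assay pair, each in
#' \[0, 1\]. Missing pairs are permitted (`NA`) and are flagged at scoring time.
#'
#' @param auc_med,auc_lo,auc_hi numeric matrices (chemicals x assays) with
#'   identical dimnames; `auc_lo <= auc_med <= auc_hi` elementwise where present.
#' @return Object of class `assay_auc_table` with elements `chem_ids`,
#'   `assay_names`, `auc_med`, `auc_lo`, `auc_hi`.
#' @export
assay_auc_table <- function(auc_med, auc_lo = auc_med, auc_hi = auc_med) {
  auc_med <- as.matrix(auc_med); auc_lo <- as.matrix(auc_lo); auc_hi <- as.matrix(auc_hi)
  if (is.null(rownames(auc_med)) || is.null(colnames(auc_med))) {
    stop("auc_med needs chemical row names and assay column names", call. = FALSE)
  }
  if (!identical(dim(auc_med), dim(auc_lo)) || !identical(dim(auc_med), dim(auc_hi))) {
    stop("auc_med, auc_lo, auc_hi must share dimensions", call. = FALSE)
  }
  chem_ids <- rownames(auc_med); assay_names <- colnames(auc_med)
  if (anyDuplicated(chem_ids)) stop("duplicate chem_ids in AUC table", call. = FALSE)
  for (m in list(auc_med, auc_lo, auc_hi)) {
    if (isTRUE(any(m < 0 | m > 1, na.rm = TRUE))) {
      stop("AUC values must lie in [0, 1]", call. = FALSE)
    }
  }
  viol <- which((auc_lo > auc_med | auc_med > auc_hi), arr.ind = TRUE)
  if (nrow(viol) > 0) {
    stop(sprintf("AUC confidence bounds violate lo <= med <= hi for chemical '%s', assay '%s'",
                 chem_ids[viol[1, 1]], assay_names[viol[1, 2]]), call. = FALSE)
  }
  dimnames(auc_lo) <- dimnames(auc_hi) <- dimnames(auc_med)
  structure(list(chem_ids = chem_ids, assay_names = assay_names,
                 auc_med = auc_med, auc_lo = auc_lo, auc_hi = auc_hi),
            class = "assay_auc_table")
}

#' @export
print.assay_auc_table <- function(x, ...) {
  cat(sprintf("<assay_auc_table> %d chemicals x %d assays (%d missing pairs)\n",
              length(x$chem_ids), length(x$assay_names), sum(is.na(x$auc_med))))
  invisible(x)
}

#' Subset-model specification
#'
#' An assay subset with non-negative weights and the activity threshold used to
#' dichotomize model AUC scores. The case-study model combines four assays
#' (receptor binding, protein dimerization, transactivation reporter, and cell
#' proliferation) with an activity threshold of 0.1 on the AUC scale.
#'
#' @param assay_names assays entering the weighted score.
#' @param weights non-negative weights, one per assay, at least one positive.
#' @param activity_threshold AUC at or above which a chemical is called active
#'   (closed comparison; default 0.1).
#' @param assay_activity_floor per-assay AUC strictly above which an assay
#'   counts as active when counting active assays (default 0).
#' @param normalize_weights divide by the weight sum so the score is a weighted
#'   mean in \[0, 1\] (default `TRUE`); `FALSE` gives the raw weighted sum.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(assay_names, weights = rep(1, length(assay_names)),
                       activity_threshold = 0.1, assay_activity_floor = 0,
                       normalize_weights = TRUE) {
  assay_names <- as.character(assay_names)
  weights <- as.numeric(weights)
  if (length(assay_names) == 0L) stop("model needs at least one assay", call. = FALSE)
  if (length(weights) != length(assay_names)) {
    stop("weights and assay_names must have equal length", call. = FALSE)
  }
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("weights must be finite and non-negative", call. = FALSE)
  }
  if (!any(weights > 0)) stop("at least one weight must be positive", call. = FALSE)
  assert_scalar_number(activity_threshold, "activity_threshold")
  assert_scalar_number(assay_activity_floor, "assay_activity_floor")
  structure(list(assay_names = assay_names,
                 weights = stats::setNames(weights, assay_names),
                 activity_threshold = activity_threshold,
                 assay_activity_floor = assay_activity_floor,
                 normalize_weights = isTRUE(normalize_weights)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %d assays, activity threshold %.3g (%s weights)\n",
              length(x$assay_names), x$activity_threshold,
              if (x$normalize_weights) "normalized" else "raw"))
  invisible(x)
}

#' Full-model reference predictions
#'
#' Per-chemical agonist AUC from the full (reference) model, used as "truth"
#' when scoring the subset model, plus the pathway model's antagonist flag
#' (true when the antagonist pathway score exceeds the agonist score). Optional
#' `full_auc_lo`/`full_auc_hi` confidence bounds are carried through when given.
#'
#' @param df data frame with columns `chem_id`, `full_auc`, `antagonist_flag`
#'   and optionally `full_auc_lo`, `full_auc_hi`.
#' @return Object of class `full_model_reference` (a validated data frame).
#' @export
full_model_reference <- function(df) {
  need <- c("chem_id", "full_auc", "antagonist_flag")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("full-model reference missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$chem_id <- as.character(df$chem_id)
  if (anyDuplicated(df$chem_id)) stop("duplicate chem_ids in full-model reference", call. = FALSE)
  df$full_auc <- as.numeric(df$full_auc)
  if (any(!is.finite(df$full_auc)) || any(df$full_auc < 0 | df$full_auc > 1)) {
    stop("full_auc must be in [0, 1]", call. = FALSE)
  }
  df$antagonist_flag <- as.logical(df$antagonist_flag)
  if (anyNA(df$antagonist_flag)) stop("antagonist_flag must be TRUE/FALSE", call. = FALSE)
  keep <- intersect(c(need, "full_auc_lo", "full_auc_hi"), names(df))
  structure(df[keep], class = c("full_model_reference", "data.frame"))
}

# ---- readers ----------------------------------------------------------------

#' Load chemical records from CSV
#'
#' Expected columns: `chem_id` (required), and optionally `casrn`, `name`,
#' `smiles`, `qsar_smiles`, `in_universe`, `in_tested_set`. Unknown columns are
#' ignored; absent optional columns are filled with empty strings / `FALSE`.
#' Duplicate identifiers are collapsed to the first occurrence with a warning
#' (a light stand-in for manual curation of duplicate registry entries).
#'
#' @param path CSV file path.
#' @return A data frame of class `chemical_table`, one row per unique chemical.
#' @export
load_chemicals <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty chemical table: ", path, call. = FALSE)
  if (!"chem_id" %in% names(df)) stop("chemical table lacks a chem_id column", call. = FALSE)
  chemical_table(df)
}

#' Validate a chemical record table
#'
#' @param df data frame with at least a `chem_id` column.
#' @return A `chemical_table` data frame with the canonical columns.
#' @export
chemical_table <- function(df) {
  if (!"chem_id" %in% names(df)) stop("chemical table lacks a chem_id column", call. = FALSE)
  df$chem_id <- as.character(df$chem_id)
  if (any(!nzchar(df$chem_id)) || anyNA(df$chem_id)) {
    stop("chem_id must be non-empty for every record", call. = FALSE)
  }
  dup <- duplicated(df$chem_id)
  if (any(dup)) {
    warning(sprintf("%d duplicate chem_id(s) collapsed to first occurrence: %s",
                    sum(dup), paste(utils::head(unique(df$chem_id[dup]), 5), collapse = ", ")),
            call. = FALSE)
    df <- df[!dup, , drop = FALSE]
  }
  for (col in c("casrn", "name", "smiles", "qsar_smiles")) {
    df[[col]] <- if (col %in% names(df)) {
      v <- as.character(df[[col]]); v[is.na(v)] <- ""; v
    } else ""
  }
  for (col in c("in_universe", "in_tested_set")) {
    df[[col]] <- if (col %in% names(df)) {
      v <- df[[col]]
      if (is.character(v)) v <- v %in% c("TRUE", "True", "true", "1")
      v <- as.logical(v); v[is.na(v)] <- FALSE; v
    } else FALSE
  }
  rownames(df) <- NULL
  structure(df[c("chem_id", "casrn", "name", "smiles", "qsar_smiles",
                 "in_universe", "in_tested_set")],
            class = c("chemical_table", "data.frame"))
}

#' Load a binary fingerprint matrix from CSV
#'
#' First column (or a column named `chem_id`) holds identifiers; every other
#' column is a feature whose values must be exactly 0 or 1. Row order is
#' preserved. Any other value is a hard error naming the offending cell.
#'
#' @param path CSV file path.
#' @return A [fingerprint_matrix()].
#' @export
load_fingerprints <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty fingerprint table: ", path, call. = FALSE)
  idcol <- if ("chem_id" %in% names(df)) "chem_id" else names(df)[1]
  ids <- as.character(df[[idcol]])
  bits <- as.matrix(df[setdiff(names(df), idcol)])
  if (!is.numeric(bits)) stop("fingerprint columns must be numeric 0/1", call. = FALSE)
  fingerprint_matrix(bits, chem_ids = ids)
}

#' Load a chemical-by-assay AUC table from long-format CSV
#'
#' Columns: `chem_id`, `assay`, `auc_med`, and optionally `auc_lo`, `auc_hi`
#' (absent bounds default to the median). Pairs not present in the file are
#' `NA` in the resulting matrices.
#'
#' @param path CSV file path.
#' @return An [assay_auc_table()].
#' @export
load_assay_aucs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("chem_id", "assay", "auc_med")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("AUC table missing column(s): ", paste(miss, collapse = ", "),
                             call. = FALSE)
  if (nrow(df) == 0L) stop("empty AUC table: ", path, call. = FALSE)
  if (!"auc_lo" %in% names(df)) df$auc_lo <- df$auc_med
  if (!"auc_hi" %in% names(df)) df$auc_hi <- df$auc_med
  chem_ids <- unique(as.character(df$chem_id))
  assays <- unique(as.character(df$assay))
  mk <- function(col) {
    m <- matrix(NA_real_, length(chem_ids), length(assays),
                dimnames = list(chem_ids, assays))
    m[cbind(match(df$chem_id, chem_ids), match(df$assay, assays))] <- as.numeric(df[[col]])
    m
  }
  assay_auc_table(mk("auc_med"), mk("auc_lo"), mk("auc_hi"))
}

#' Load a subset-model specification from YAML
#'
#' Keys: `assays` (list), `weights` (list, same length), and optionally
#' `activity_threshold`, `assay_activity_floor`, `normalize_weights`.
#'
#' @param path YAML file path.
#' @return A [model_spec()].
#' @export
load_model_spec <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$assays)) stop("model spec lacks `assays`", call. = FALSE)
  model_spec(assay_names = unlist(y$assays),
             weights = unlist(y$weights %||% rep(1, length(y$assays))),
             activity_threshold = y$activity_threshold %||% 0.1,
             assay_activity_floor = y$assay_activity_floor %||% 0,
             normalize_weights = y$normalize_weights %||% TRUE)
}

#' Load full-model reference predictions from CSV
#'
#' Columns: `chem_id`, `full_auc`, `antagonist_flag`, and optionally
#' `full_auc_lo`, `full_auc_hi`.
#'
#' @param path CSV file path.
#' @return A [full_model_reference()].
#' @export
load_full_model <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty full-model reference: ", path, call. = FALSE)
  full_model_reference(df)
}

# ---- writers (round-trip partners of the readers) ---------------------------

#' Write pipeline tables to CSV
#'
#' Round-trip partners of the `load_*` readers: integers are reproduced
#' bit-exactly and reals to at least 12 significant digits.
#'
#' @param x object to write.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_chemicals <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chemicals
#' @export
write_fingerprints <- function(x, path) {
  stopifnot(inherits(x, "fingerprint_matrix"))
  df <- data.frame(chem_id = x$chem_ids, x$bits, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chemicals
#' @export
write_assay_aucs <- function(x, path) {
  stopifnot(inherits(x, "assay_auc_table"))
  idx <- which(!is.na(x$auc_med), arr.ind = TRUE)
  df <- data.frame(chem_id = x$chem_ids[idx[, 1]],
                   assay = x$assay_names[idx[, 2]],
                   auc_med = format(x$auc_med[idx], digits = 15),
                   auc_lo = format(x$auc_lo[idx], digits = 15),
                   auc_hi = format(x$auc_hi[idx], digits = 15))
  df <- df[order(match(df$chem_id, x$chem_ids), match(df$assay, x$assay_names)), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_chemicals
#' @export
write_full_model <- function(x, path) {
  df <- as.data.frame(x)
  for (col in intersect(c("full_auc", "full_auc_lo", "full_auc_hi"), names(df))) {
    df[[col]] <- format(df[[col]], digits = 15)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_chemicals
#' @export
write_model_spec <- function(x, path) {
  stopifnot(inherits(x, "model_spec"))
  yaml::write_yaml(list(assays = as.list(x$assay_names),
                        weights = as.list(unname(x$weights)),
                        activity_threshold = x$activity_threshold,
                        assay_activity_floor = x$assay_activity_floor,
                        normalize_weights = x$normalize_weights), path)
  invisible(path)
}

# ---- joining ----------------------------------------------------------------

#' Join chemicals, fingerprints, AUC table and reference into one bundle
#'
#' Intersects the data sources on `chem_id`, logs per-source counts (universe
#' size, tested size, overlap), and lists chemicals that cannot enter
#' clustering for lack of a fingerprint. No chemical is silently dropped:
#' everything excluded is enumerated in the returned bundle.
#'
#' @param chems a `chemical_table`.
#' @param fps a [fingerprint_matrix()].
#' @param aucs an [assay_auc_table()].
#' @param ref a [full_model_reference()].
#' @return A list of class `edsp_bundle` with elements `chemicals`,
#'   `fingerprints`, `aucs`, `ref`, `universe_ids`, `tested_ids`,
#'   `missing_fingerprint`, and `counts`.
#' @export
join_datasets <- function(chems, fps, aucs, ref) {
  stopifnot(inherits(fps, "fingerprint_matrix"), inherits(aucs, "assay_auc_table"))
  chems <- chemical_table(as.data.frame(chems))
  ref <- full_model_reference(as.data.frame(ref))

  universe_ids <- chems$chem_id[chems$in_universe]
  tested_ids <- chems$chem_id[chems$in_tested_set]
  tested_scored <- intersect(intersect(tested_ids, aucs$chem_ids), ref$chem_id)
  if (length(tested_scored) == 0L) {
    stop("no overlap between the tested set and the assay AUC table / reference",
         call. = FALSE)
  }
  has_fp <- chems$chem_id %in% fps$chem_ids
  missing_fp <- chems$chem_id[(chems$in_universe | chems$in_tested_set) & !has_fp]
  universe_clust <- setdiff(universe_ids, missing_fp)
  tested_mapped <- setdiff(tested_scored, missing_fp)

  counts <- c(n_records = nrow(chems),
              n_universe = length(universe_ids),
              n_tested = length(tested_ids),
              n_overlap = length(intersect(universe_ids, tested_ids)),
              n_tested_scored = length(tested_scored),
              n_missing_fingerprint = length(missing_fp))
  message(sprintf(
    "joined datasets: %d records; universe %d; tested %d (overlap %d); scored %d; %d lacking fingerprints",
    counts[["n_records"]], counts[["n_universe"]], counts[["n_tested"]],
    counts[["n_overlap"]], counts[["n_tested_scored"]], counts[["n_missing_fingerprint"]]))
  if (length(missing_fp) > 0) {
    message("excluded from clustering (no fingerprint): ",
            paste(utils::head(missing_fp, 10), collapse = ", "),
            if (length(missing_fp) > 10) ", ..." else "")
  }

  structure(list(chemicals = chems, fingerprints = fps, aucs = aucs, ref = ref,
                 universe_ids = universe_clust, tested_ids = tested_mapped,
                 missing_fingerprint = missing_fp, counts = counts),
            class = "edsp_bundle")
}

#' @export
print.edsp_bundle <- function(x, ...) {
  cat("<edsp_bundle>\n")
  for (nm in names(x$counts)) cat(sprintf("  %-24s %d\n", nm, x$counts[[nm]]))
  invisible(x)
}
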