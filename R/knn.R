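#' @title KNN mapping of tested chemicals into universe clusters
#' @description Chemicals screened in the assay battery but outside (or
#'   inside) the clustered universe are placed into clusters by k-nearest
#'   neighbours under Tanimoto distance. The neighbourhood size k is selected
#'   by an 80/20 split of the clustered universe: for each candidate k the
#'   held-out chemicals are re-assigned from the training portion and the k
#'   with the best agreement against the dendrogram labels wins (ties go to
#'   the smallest k). A chemical identical to a training chemical always maps
#'   to that chemical's own cluster at k = 1.
#' @name knn_map
NULL

#' Assign query chemicals to clusters by k-nearest neighbours
#'
#' Majority vote among the k nearest training chemicals by Tanimoto distance.
#' Distance ties are broken by the lexicographically lowest training
#' `chem_id`; vote ties are broken by the cluster of the single nearest
#' neighbour.
#'
#' @param train_fps training [fingerprint_matrix()].
#' @param train_assign [cluster_assignment()] covering every training chemical.
#' @param query_fps query [fingerprint_matrix()] (same feature space).
#' @param k neighbourhood size, at least 1 and at most the training set size.
#' @return A [cluster_assignment()] for the query chemicals. Labels are taken
#'   verbatim from `train_assign` (no relabelling), so they remain comparable
#'   with the universe clustering.
#' @export
knn_assign <- function(train_fps, train_assign, query_fps, k = 1) {
  stopifnot(inherits(train_fps, "fingerprint_matrix"),
            inherits(query_fps, "fingerprint_matrix"),
            inherits(train_assign, "cluster_assignment"))
  if (length(train_fps$chem_ids) == 0L) stop("empty training set", call. = FALSE)
  assert_scalar_number(k, "k")
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k > length(train_fps$chem_ids)) {
    stop("k exceeds the training set size", call. = FALSE)
  }
  if (length(train_fps$feature_names) != length(query_fps$feature_names)) {
    stop("train and query fingerprints must share the feature space", call. = FALSE)
  }
  miss <- setdiff(train_fps$chem_ids, names(train_assign))
  if (length(miss) > 0) {
    stop("training chemicals without cluster labels: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  train_cl <- unclass(train_assign)[train_fps$chem_ids]

  d <- tanimoto_cross(query_fps$bits, train_fps$bits)
  # secondary sort key: lexicographic rank of the training identifier
  id_rank <- rank(train_fps$chem_ids, ties.method = "first")
  out <- integer(nrow(d))
  for (i in seq_len(nrow(d))) {
    ord <- order(d[i, ], id_rank)[seq_len(k)]
    votes <- table(train_cl[ord])
    winners <- as.integer(names(votes)[votes == max(votes)])
    out[i] <- if (length(winners) == 1L) winners else train_cl[ord[1L]]
  }
  # bypass first-appearance relabelling: keep the universe labels verbatim
  res <- cluster_assignment(out, chem_ids = query_fps$chem_ids,
                            cut_height = attr(train_assign, "cut_height"),
                            linkage_variant = attr(train_assign, "linkage_variant"))
  res[] <- as.integer(out)
  res
}

#' Select the KNN neighbourhood size by a held-out split
#'
#' Splits the clustered universe uniformly at random (not stratified by
#' cluster, so held-out members of singleton clusters are unclassifiable and
#' cap the attainable accuracy below 1) into training and test portions,
#' re-assigns the test portion from the training portion for each candidate
#' k, and scores agreement with the known dendrogram labels.
#'
#' @param fps [fingerprint_matrix()] of the clustered universe.
#' @param assign [cluster_assignment()] for every chemical in `fps`.
#' @param k_candidates candidate neighbourhood sizes (default 1..5).
#' @param split_fraction training fraction (default 0.8).
#' @param seed required RNG seed for the split (no hidden default).
#' @return Object of class `k_selection`: list with `k_candidates`,
#'   `accuracy_by_k`, `chosen_k`, `split_fraction`, `seed`, `n_train`,
#'   `n_test`.
#' @export
select_k <- function(fps, assign, k_candidates = 1:5, split_fraction = 0.8, seed) {
  stopifnot(inherits(fps, "fingerprint_matrix"), inherits(assign, "cluster_assignment"))
  if (missing(seed) || is.null(seed)) stop("`seed` is required for the split", call. = FALSE)
  assert_scalar_number(split_fraction, "split_fraction")
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop("split_fraction must be strictly between 0 and 1", call. = FALSE)
  }
  miss <- setdiff(fps$chem_ids, names(assign))
  if (length(miss) > 0) {
    stop("chemicals without cluster labels: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  n <- length(fps$chem_ids)
  n_train <- max(1L, floor(n * split_fraction))
  train_idx <- with_seed(seed, sort(sample.int(n, n_train)))
  test_idx <- setdiff(seq_len(n), train_idx)
  if (length(test_idx) == 0L) stop("split left no test chemicals", call. = FALSE)

  train_fps <- fp_subset(fps, fps$chem_ids[train_idx])
  test_fps <- fp_subset(fps, fps$chem_ids[test_idx])
  truth <- unclass(assign)[fps$chem_ids[test_idx]]

  acc <- stats::setNames(rep(NA_real_, length(k_candidates)),
                         as.character(k_candidates))
  for (k in k_candidates) {
    if (k > n_train) {
      warning(sprintf("k = %d exceeds training size %d; skipped", k, n_train),
              call. = FALSE)
      next
    }
    pred <- knn_assign(train_fps, assign, test_fps, k = k)
    acc[as.character(k)] <- mean(unclass(pred) == truth)
  }
  if (all(is.na(acc))) stop("no usable k candidate", call. = FALSE)
  best <- max(acc, na.rm = TRUE)
  chosen <- min(k_candidates[!is.na(acc) & acc == best])
  structure(list(k_candidates = as.integer(k_candidates), accuracy_by_k = acc,
                 chosen_k = as.integer(chosen), split_fraction = split_fraction,
                 seed = seed, n_train = n_train, n_test = length(test_idx)),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("<k_selection> chosen k = %d (train %d / test %d, seed %s)\n",
              x$chosen_k, x$n_train, x$n_test, format(x$seed)))
  for (k in names(x$accuracy_by_k)) {
    cat(sprintf("  k = %s: accuracy %s\n", k, format(x$accuracy_by_k[[k]], digits = 4)))
  }
  invisible(x)
}

#' Cluster coverage of a mapped chemical set
#'
#' How many distinct universe clusters received at least one mapped chemical.
#'
#' @param universe_assign [cluster_assignment()] of the clustered universe.
#' @param query_assign [cluster_assignment()] returned by [knn_assign()].
#' @return List with `n_universe_clusters`, `n_covered_clusters`,
#'   `coverage_fraction`.
#' @export
cluster_coverage <- function(universe_assign, query_assign) {
  u <- unique(unclass(universe_assign))
  q <- unique(unclass(query_assign))
  list(n_universe_clusters = length(u),
       n_covered_clusters = length(intersect(u, q)),
       coverage_fraction = length(intersect(u, q)) / length(u))
}
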