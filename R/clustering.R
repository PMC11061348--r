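#' @title Structural clustering of a chemical universe
#' @description Tanimoto (Jaccard) distance over binary substructure
#'   fingerprints, agglomerative Ward clustering of the resulting distance
#'   matrix, and a fixed-height dendrogram cut. The Ward dialect matters for
#'   reproducibility: `ward_d2` operates on squared distances (consistent with
#'   Ward's variance objective applied to a distance matrix) and is the
#'   default; `ward_d` applies the classic Lance-Williams update to the raw
#'   distances. Cluster counts at a given cut height are dialect-sensitive.
#' @name clustering
NULL

#' Tanimoto distance between two binary fingerprints
#'
#' `1 - c / (a + b - c)` where `c` is the number of shared on-bits and `a`,
#' `b` the on-bit counts of each vector. Two all-zero fingerprints are treated
#' as identical (distance 0, with a degenerate-fingerprint warning); an
#' all-zero vector against a non-zero one is maximally distant (1).
#'
#' @param fp_a,fp_b binary vectors of equal length (0/1).
#' @return A distance in \[0, 1\].
#' @export
#' @examples
#' tanimoto_distance(c(1, 1, 1, 0), c(0, 1, 1, 1)) # shares 2 of 4 union bits -> 0.5
tanimoto_distance <- function(fp_a, fp_b) {
  if (length(fp_a) != length(fp_b)) {
    stop("fingerprint length mismatch: ", length(fp_a), " vs ", length(fp_b),
         call. = FALSE)
  }
  if (!all(fp_a %in% c(0, 1)) || !all(fp_b %in% c(0, 1))) {
    stop("fingerprints must be binary 0/1 vectors", call. = FALSE)
  }
  a <- sum(fp_a); b <- sum(fp_b); c <- sum(fp_a == 1 & fp_b == 1)
  if (a == 0 && b == 0) {
    warning("both fingerprints are all-zero (degenerate); returning distance 0",
            call. = FALSE)
    return(0)
  }
  if (a == 0 || b == 0) return(1)
  1 - c / (a + b - c)
}

# Cross-set Tanimoto distance via bit-matrix algebra; rows of A vs rows of B.
# All-zero/all-zero pairs come out 0, all-zero vs non-zero pairs come out 1.
tanimoto_cross <- function(A, B) {
  C <- A %*% t(B)
  a <- rowSums(A); b <- rowSums(B)
  denom <- outer(a, b, "+") - C
  d <- 1 - C / denom
  d[denom == 0] <- 0 # both fingerprints empty
  dimnames(d) <- list(rownames(A), rownames(B))
  d
}

#' Pairwise Tanimoto distance matrix
#'
#' @param fps a [fingerprint_matrix()] with at least two chemicals.
#' @return Object of class `distance_matrix`: list with `chem_ids` and the
#'   symmetric matrix `d` (zero diagonal, entries in \[0, 1\]).
#' @export
pairwise_distances <- function(fps) {
  stopifnot(inherits(fps, "fingerprint_matrix"))
  n <- length(fps$chem_ids)
  if (n < 2) stop("need at least 2 chemicals to compute pairwise distances", call. = FALSE)
  zero_rows <- rowSums(fps$bits) == 0
  if (any(zero_rows)) {
    warning(sprintf("%d all-zero (degenerate) fingerprint(s): %s", sum(zero_rows),
                    paste(utils::head(fps$chem_ids[zero_rows], 5), collapse = ", ")),
            call. = FALSE)
  }
  d <- tanimoto_cross(fps$bits, fps$bits)
  diag(d) <- 0
  d <- (d + t(d)) / 2 # enforce exact symmetry against float noise
  structure(list(chem_ids = fps$chem_ids, d = d), class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %d chemicals (mean off-diagonal distance %.3f)\n",
              length(x$chem_ids),
              mean(x$d[upper.tri(x$d)])))
  invisible(x)
}

#' Ward hierarchical clustering with a fixed-height cut
#'
#' Builds an agglomerative Ward linkage tree on the distance matrix and cuts
#' it at an absolute height, relabelling clusters 1..K in order of first
#' member appearance. Tie-breaking among equal-height merges follows the
#' linkage implementation (lowest pair index) and is implementation-defined;
#' permuting the input order changes labels but not the partition for data
#' without exact merge ties.
#'
#' @param d a [pairwise_distances()] result.
#' @param cut_height positive absolute cut height on the linkage tree.
#' @param linkage_variant `"ward_d2"` (default) or `"ward_d"`.
#' @return A [cluster_assignment()] covering every chemical in `d`.
#' @export
ward_cut <- function(d, cut_height = 1, linkage_variant = c("ward_d2", "ward_d")) {
  stopifnot(inherits(d, "distance_matrix"))
  linkage_variant <- match.arg(linkage_variant)
  assert_scalar_number(cut_height, "cut_height")
  if (cut_height <= 0) stop("cut_height must be positive", call. = FALSE)
  if (any(!is.finite(d$d))) stop("non-finite distances", call. = FALSE)
  method <- c(ward_d2 = "ward.D2", ward_d = "ward.D")[[linkage_variant]]
  hc <- stats::hclust(stats::as.dist(d$d), method = method)
  labels <- stats::cutree(hc, h = cut_height)
  cluster_assignment(labels, chem_ids = d$chem_ids,
                     cut_height = cut_height, linkage_variant = linkage_variant)
}

#' Cluster size profile
#'
#' Sizes per cluster plus singleton/doubleton counts — the quantities used to
#' judge a cut height (avoid single-chemical clusters, limit two-chemical
#' clusters, without merging dissimilar chemistry).
#'
#' @param assign a [cluster_assignment()].
#' @return List with `sizes` (data frame `cluster_id`, `size`), `n_clusters`,
#'   `n_chemicals`, `n_singletons`, `n_doubletons`.
#' @export
cluster_size_profile <- function(assign) {
  stopifnot(inherits(assign, "cluster_assignment"))
  tab <- table(unclass(assign))
  sizes <- data.frame(cluster_id = as.integer(names(tab)), size = as.integer(tab))
  sizes <- sizes[order(sizes$cluster_id), , drop = FALSE]
  rownames(sizes) <- NULL
  list(sizes = sizes,
       n_clusters = nrow(sizes),
       n_chemicals = sum(sizes$size),
       n_singletons = sum(sizes$size == 1L),
       n_doubletons = sum(sizes$size == 2L))
}
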