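#' @title Synthetic chemical universes and assay AUC tables
#' @description Generators with known ground truth for every pipeline stage.
#'
#'   The fingerprint generator plants a block structure: each cluster owns a
#'   random mask of `mask_size` feature bits; members switch mask bits on with
#'   probability `within_profile_on_prob` and every other bit on with
#'   probability `background_on_prob`. With the defaults, within-cluster
#'   Tanimoto distances concentrate well below between-cluster distances, so
#'   the planted partition is recoverable by Ward clustering.
#'
#'   The assay generator draws each chemical from a mixture of five activity
#'   archetypes chosen to emulate the composition of a screened chemical
#'   inventory: `strong_agonist` (high AUC in 3-4 assays, clearly active in
#'   the full model), `weak_agonist` (modest AUC in 2-3 assays, full-model
#'   score near the 0.1 threshold), `antagonist_like` (high AUC confined to
#'   the binding/dimerization assays shared between agonist and antagonist
#'   pathways, full-model score below threshold, antagonist flag set),
#'   `inactive` (all zeros), and `borderline` (subset score straddling the
#'   threshold with overlapping confidence interval, full model inactive).
#'   Noise perturbs only assay-archetype pairs with a nonzero mean — inactive
#'   pairs score exactly 0, as in real AUC tables — so active-assay counts are
#'   archetype-determined and planted confusion/triage counts are exact at
#'   zero noise.
#' @name synthetic_data
NULL

#' Specification of a planted-cluster fingerprint universe
#'
#' @param n_clusters number of planted clusters.
#' @param cluster_sizes integer vector of members per cluster (recycled to
#'   `n_clusters`).
#' @param n_features fingerprint width (default 729, the ToxPrint library size).
#' @param within_profile_on_prob probability a member sets each of its
#'   cluster's mask bits (default 0.9).
#' @param background_on_prob probability of setting any off-mask bit
#'   (default 0.02).
#' @param mask_size bits in each cluster's characteristic mask (default 40).
#' @param seed required RNG seed.
#' @return Object of class `universe_spec`.
#' @export
universe_spec <- function(n_clusters = 10, cluster_sizes = 20, n_features = 729,
                          within_profile_on_prob = 0.9, background_on_prob = 0.02,
                          mask_size = 40, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(n_clusters >= 1, all(cluster_sizes >= 1), n_features >= 1,
            mask_size >= 1, mask_size <= n_features,
            within_profile_on_prob >= 0, within_profile_on_prob <= 1,
            background_on_prob >= 0, background_on_prob <= 1)
  structure(list(n_clusters = as.integer(n_clusters),
                 cluster_sizes = rep_len(as.integer(cluster_sizes), n_clusters),
                 n_features = as.integer(n_features),
                 within_profile_on_prob = within_profile_on_prob,
                 background_on_prob = background_on_prob,
                 mask_size = as.integer(mask_size),
                 seed = seed),
            class = "universe_spec")
}

# Draw fingerprints for chemicals with given planted cluster labels, using the
# per-cluster masks. Pure function of the RNG state.
draw_members <- function(masks, labels, n_features, within_p, background_p) {
  n <- length(labels)
  bits <- matrix(stats::rbinom(n * n_features, 1L, background_p), nrow = n)
  for (i in seq_len(n)) {
    m <- masks[[labels[i]]]
    bits[i, m] <- stats::rbinom(length(m), 1L, within_p)
  }
  bits
}

#' Generate a fingerprint universe with planted clusters
#'
#' @param spec a [universe_spec()].
#' @param id_prefix identifier prefix (default `"SYN"`).
#' @return List with `chemicals` (a `chemical_table`, all `in_universe`),
#'   `fingerprints` (a [fingerprint_matrix()]), `truth` (the planted
#'   [cluster_assignment()]), and `masks` (per-cluster feature masks, for
#'   generating additional chemicals from the same structure).
#' @export
gen_universe <- function(spec, id_prefix = "SYN") {
  stopifnot(inherits(spec, "universe_spec"))
  labels <- rep(seq_len(spec$n_clusters), times = spec$cluster_sizes)
  n <- length(labels)
  ids <- sprintf("%s-%06d", id_prefix, seq_len(n))

  res <- with_seed(spec$seed, {
    masks <- lapply(seq_len(spec$n_clusters), function(i) {
      sort(sample.int(spec$n_features, spec$mask_size))
    })
    bits <- draw_members(masks, labels, spec$n_features,
                         spec$within_profile_on_prob, spec$background_on_prob)
    list(masks = masks, bits = bits)
  })
  fps <- fingerprint_matrix(res$bits, chem_ids = ids,
                            feature_names = sprintf("bit%03d", seq_len(spec$n_features)))
  chems <- chemical_table(data.frame(chem_id = ids,
                                     name = ids,
                                     in_universe = TRUE,
                                     in_tested_set = FALSE))
  truth <- cluster_assignment(labels, chem_ids = ids, linkage_variant = "planted")
  list(chemicals = chems, fingerprints = fps, truth = truth, masks = res$masks)
}

#' Generate extra chemicals from an existing universe's cluster masks
#'
#' Used to build a tested set that extends beyond the clustered universe while
#' still belonging, structurally, to its planted clusters (so the KNN mapping
#' has a known right answer).
#'
#' @param universe result of [gen_universe()].
#' @param spec the same [universe_spec()] used for the universe.
#' @param n number of extra chemicals.
#' @param seed RNG seed.
#' @param id_prefix identifier prefix (default `"EXT"`).
#' @return List with `chemicals`, `fingerprints`, `truth` for the new set.
#' @export
gen_cluster_members <- function(universe, spec, n, seed, id_prefix = "EXT") {
  stopifnot(inherits(spec, "universe_spec"), n >= 1)
  ids <- sprintf("%s-%06d", id_prefix, seq_len(n))
  res <- with_seed(seed, {
    labels <- sample.int(spec$n_clusters, n, replace = TRUE)
    bits <- draw_members(universe$masks, labels, spec$n_features,
                         spec$within_profile_on_prob, spec$background_on_prob)
    list(labels = labels, bits = bits)
  })
  fps <- fingerprint_matrix(res$bits, chem_ids = ids,
                            feature_names = sprintf("bit%03d", seq_len(spec$n_features)))
  chems <- chemical_table(data.frame(chem_id = ids, name = ids,
                                     in_universe = FALSE, in_tested_set = TRUE))
  truth <- cluster_assignment(res$labels, chem_ids = ids, linkage_variant = "planted")
  truth[] <- as.integer(res$labels) # keep universe cluster labels verbatim
  list(chemicals = chems, fingerprints = fps, truth = truth)
}

#' Default assay names of the case-study 4-assay subset model
#'
#' Receptor binding, protein dimerization, transactivation reporter, and cell
#' proliferation, in that order.
#' @return Character vector of length 4.
#' @export
default_subset_assays <- function() {
  c("NVS_NR_hER", "OT_ER_ERaERb_1440", "ATG_ERa_TRANS", "ACEA_T47D_80hr_Positive")
}

#' Specification of the activity archetype mixture
#'
#' Default mixture weights mirror the composition observed when a large
#' screened inventory is compared against a full-model reference: about 6%
#' clear true positives with a small weak-agonist minority, about 7% subset
#' false positives of which roughly one in ten is antagonist-driven and the
#' rest are low-score borderline actives, and an inactive majority.
#'
#' @param weights named mixture weights over
#'   `strong_agonist`, `weak_agonist`, `antagonist_like`, `inactive`,
#'   `borderline`; non-negative, normalized internally.
#' @param assay_names assay columns to generate (default
#'   [default_subset_assays()]).
#' @param noise_sd sd of the truncated-normal perturbation applied to nonzero
#'   assay means and to the full-model score (default 0.03).
#' @param ci_halfwidth half-width of the per-assay 95% interval around the
#'   median, clipped to \[0, 1\] (default 0.08).
#' @param seed required RNG seed.
#' @return Object of class `archetype_spec`.
#' @export
archetype_spec <- function(weights = c(strong_agonist = 0.055,
                                       weak_agonist = 0.012,
                                       antagonist_like = 0.007,
                                       inactive = 0.862,
                                       borderline = 0.064),
                           assay_names = default_subset_assays(),
                           noise_sd = 0.03, ci_halfwidth = 0.08, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  need <- c("strong_agonist", "weak_agonist", "antagonist_like", "inactive", "borderline")
  if (!all(need %in% names(weights))) {
    stop("weights must be named with all five archetypes", call. = FALSE)
  }
  weights <- weights[need]
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be non-negative with positive sum", call. = FALSE)
  }
  stopifnot(length(assay_names) == 4L, noise_sd >= 0, ci_halfwidth >= 0)
  structure(list(weights = weights / sum(weights),
                 assay_names = as.character(assay_names),
                 noise_sd = noise_sd, ci_halfwidth = ci_halfwidth, seed = seed),
            class = "archetype_spec")
}

# Archetype rulebook. Assay order: binding, dimerization, transactivation,
# proliferation. Each archetype carries one or two activity patterns (chosen
# per chemical with prob `p`): the per-assay mean AUC on active assays, and
# the full-model mean score. Calls at zero noise are archetype-determined:
# strong/weak -> TP, antagonist/borderline -> FP, inactive -> TN.
archetype_rules <- function() {
  list(
    strong_agonist = list(full_mean = NA, antagonist = FALSE, patterns = list(
      list(p = 0.5, means = c(0.55, 0.55, 0.55, 0.55)),
      list(p = 0.5, means = c(0, 0.55, 0.55, 0.55)))),
    weak_agonist = list(full_mean = 0.13, antagonist = FALSE, patterns = list(
      list(p = 0.5, means = c(0, 0, 0.22, 0.22)),
      list(p = 0.5, means = c(0, 0.18, 0.18, 0.18)))),
    antagonist_like = list(full_mean = 0.03, antagonist = TRUE, patterns = list(
      list(p = 0.5, means = c(0.5, 0.5, 0, 0)),
      list(p = 0.5, means = c(0.5, 0.5, 0.15, 0)))),
    inactive = list(full_mean = 0, antagonist = FALSE, patterns = list(
      list(p = 1, means = c(0, 0, 0, 0)))),
    borderline = list(full_mean = 0.04, antagonist = FALSE, patterns = list(
      list(p = 0.8, means = c(0, 0, 0.26, 0.26)),
      list(p = 0.2, means = c(0, 0.21, 0.21, 0.21))))
  )
}

#' Generate an assay AUC table and full-model reference from archetypes
#'
#' @param chem_ids chemicals to generate.
#' @param spec an [archetype_spec()].
#' @return List with `aucs` (an [assay_auc_table()]), `ref` (a
#'   [full_model_reference()]), and `archetypes` (named character vector of
#'   planted labels).
#' @export
gen_assay_table <- function(chem_ids, spec) {
  stopifnot(inherits(spec, "archetype_spec"))
  chem_ids <- as.character(chem_ids)
  n <- length(chem_ids)
  if (n == 0L) stop("no chemicals to generate", call. = FALSE)
  rules <- archetype_rules()

  res <- with_seed(spec$seed, {
    arch <- sample(names(spec$weights), n, replace = TRUE, prob = spec$weights)
    med <- matrix(0, n, 4L)
    full <- numeric(n)
    flag <- logical(n)
    for (i in seq_len(n)) {
      rule <- rules[[arch[i]]]
      probs <- vapply(rule$patterns, `[[`, numeric(1), "p")
      pat <- rule$patterns[[sample.int(length(probs), 1L, prob = probs)]]
      means <- pat$means
      active <- means > 0
      vals <- means
      if (spec$noise_sd > 0 && any(active)) {
        vals[active] <- clip01(means[active] + stats::rnorm(sum(active), 0, spec$noise_sd))
      }
      med[i, ] <- vals
      base_full <- if (is.na(rule$full_mean)) mean(vals[active]) else rule$full_mean
      full[i] <- if (spec$noise_sd > 0 && base_full > 0) {
        clip01(base_full + stats::rnorm(1L, 0, spec$noise_sd))
      } else base_full
      flag[i] <- rule$antagonist
    }
    list(arch = arch, med = med, full = full, flag = flag)
  })

  dimnames(res$med) <- list(chem_ids, spec$assay_names)
  lo <- pmax(res$med - spec$ci_halfwidth, 0)
  hi <- pmin(res$med + spec$ci_halfwidth, 1)
  # inactive pairs keep degenerate intervals at zero
  lo[res$med == 0] <- 0
  hi[res$med == 0] <- 0
  aucs <- assay_auc_table(res$med, lo, hi)
  ref <- full_model_reference(data.frame(chem_id = chem_ids,
                                         full_auc = res$full,
                                         antagonist_flag = res$flag))
  list(aucs = aucs, ref = ref,
       archetypes = stats::setNames(res$arch, chem_ids))
}

#' Expected confusion label for each archetype at zero noise
#'
#' The archetype-to-call mapping implied by the generator rulebook and the
#' default 0.1 activity threshold, used to compute planted confusion counts.
#'
#' @return Named character vector over the five archetypes.
#' @export
archetype_expected_confusion <- function() {
  c(strong_agonist = "TP", weak_agonist = "TP", antagonist_like = "FP",
    inactive = "TN", borderline = "FP")
}
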