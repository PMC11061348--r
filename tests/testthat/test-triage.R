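test_that("true-positive score quantile uses linear interpolation", {
  tp3 <- make_preds(c("a", "b", "c"), full_auc = 0.5, subset_auc_med = 0.2)
  expect_equal(tp_auc_quantile(tp3, 0.25), 0.2) # constant scores
  expect_equal(tp_auc_quantile(tp3, 0.9), 0.2)

  tp4 <- make_preds(c("a", "b", "c", "d"), full_auc = 0.5,
                    subset_auc_med = c(0.1, 0.2, 0.3, 0.4))
  # type-7 linear interpolation by hand: h = 1 + 0.25 * 3 = 1.75 -> 0.175
  expect_equal(tp_auc_quantile(tp4, 0.25), 0.175)

  none <- make_preds("x", full_auc = 0, subset_auc_med = 0)
  expect_error(tp_auc_quantile(none), "no true-positive")
})

test_that("confidence-interval overlap uses closed intervals on either model", {
  p <- make_preds(c("a", "b", "c"),
                  full_auc = 0, subset_auc_med = c(0.132, 0.2, 0.2),
                  subset_auc_lo = c(0.05, 0.15, 0.1),
                  subset_auc_hi = c(0.20, 0.30, 0.3))
  expect_message(hit <- ci_overlaps_threshold(p), "subset interval only")
  expect_equal(hit, c(TRUE, FALSE, TRUE)) # boundary lo = 0.1 counts (closed)

  # a full-model interval straddling the threshold rescues a non-overlapping subset interval
  p$full_auc_lo <- c(0, 0.05, 0)
  p$full_auc_hi <- c(0.01, 0.15, 0.01)
  expect_equal(ci_overlaps_threshold(p), c(TRUE, TRUE, TRUE))
})

test_that("false positives land in the first matching category of the ordered cascade", {
  preds <- make_preds(
    chem_id = c("tp1", "tp2", "tp3", "tp4",          # quartile of (.2 .3 .4 .5) = 0.275
                "fpA", "fpB", "fpC", "fpD", "tn1"),
    full_auc       = c(0.5, 0.5, 0.5, 0.5, 0, 0, 0, 0, 0),
    subset_auc_med = c(0.2, 0.3, 0.4, 0.5, 0.12, 0.12, 0.4, 0.4, 0),
    antagonist_flag = c(rep(FALSE, 4), TRUE, FALSE, FALSE, FALSE, FALSE),
    n_active_assays = c(4, 4, 4, 4, 4, 4, 2, 3, 0))
  rep <- triage_false_positives(preds, triage_config())
  expect_equal(rep$tp_quantile_value, 0.275)
  got <- setNames(as.character(rep$table$category), rep$table$chem_id)
  # fpA is an antagonist AND below the quartile: the flag rule fires first
  expect_equal(got[["fpA"]], "antagonist_flagged")
  expect_equal(got[["fpB"]], "below_tp_quartile")
  expect_equal(got[["fpC"]], "low_assay_count")
  expect_equal(got[["fpD"]], "residual_high_priority")
  # exhaustive and disjoint: counts sum to the FP total
  expect_equal(sum(rep$counts), rep$n_fp)
  expect_equal(rep$n_fp, 4L)

  # rule-order sensitivity: quartile-first assignment would differ for fpA,
  # guarding against accidental reordering of the cascade
  quartile_first <- ifelse(preds$subset_auc_med < 0.275, "below_tp_quartile",
                           ifelse(preds$antagonist_flag, "antagonist_flagged", "other"))
  expect_false(quartile_first[preds$chem_id == "fpA"] == got[["fpA"]])
})

test_that("an FP exactly at the quartile is not down-weighted (strict comparison)", {
  preds <- make_preds(
    chem_id = c("t1", "t2", "t3", "fp_at", "fp_under"),
    full_auc       = c(0.5, 0.5, 0.5, 0, 0),
    subset_auc_med = c(0.25, 0.25, 0.25, 0.25, 0.2499),
    n_active_assays = 4)
  rep <- triage_false_positives(preds)
  got <- setNames(as.character(rep$table$category), rep$table$chem_id)
  expect_equal(got[["fp_at"]], "residual_high_priority")
  expect_equal(got[["fp_under"]], "below_tp_quartile")
})

test_that("prioritization ranks by assay-count rule then score, and rescues cluster mates", {
  preds <- make_preds(
    chem_id = c("hi2", "lo4", "neg1", "neg2", "tn"),
    full_auc       = c(0.5, 0.5, 0, 0.0, 0),
    subset_auc_med = c(0.30, 0.15, 0.05, 0.02, 0),
    n_active_assays = c(2, 4, 1, 0, 0))
  assign <- assign_clusters(preds$chem_id, c(1, 2, 1, 3, 3))
  pri <- prioritization_list(preds, assign)
  # the 4-assay-active chemical outranks the higher-AUC 2-assay one
  expect_equal(pri$ranked$chem_id, c("lo4", "hi2"))
  expect_equal(pri$ranked$meets_assay_rule, c(TRUE, FALSE))
  # cluster 1 contains a positive: its negative member is rescued
  expect_true(pri$cluster_enrichment$marked[pri$cluster_enrichment$cluster_id == 1])
  expect_equal(pri$rescued$chem_id, "neg1")
  expect_equal(pri$cluster_enrichment$positive_fraction[
    pri$cluster_enrichment$cluster_id == 3], 0)

  # no positives: empty ranking and no marked clusters
  nothing <- make_preds(c("a", "b"), full_auc = 0, subset_auc_med = 0)
  pri0 <- prioritization_list(nothing, assign_clusters(c("a", "b"), c(1, 1)))
  expect_equal(nrow(pri0$ranked), 0L)
  expect_false(any(pri0$cluster_enrichment$marked))
  expect_equal(nrow(pri0$rescued), 0L)
})
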