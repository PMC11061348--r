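test_that("a ten-chemical cluster with nine concordant actives and one false positive scores as expected", {
  preds <- make_preds(chem_id = sprintf("c%02d", 1:10),
                      full_auc = c(rep(0.5, 9), 0),
                      subset_auc_med = c(rep(0.5, 9), 0.33))
  assign <- assign_clusters(preds$chem_id, rep(1, 10))
  st <- cluster_confusion(preds, assign)$stats
  expect_equal(st[, c("tp", "fp", "tn", "fn")],
               data.frame(tp = 9L, fp = 1L, tn = 0L, fn = 0L))
  expect_equal(st$accuracy, 0.9)
  expect_equal(st$sensitivity, 1)
  expect_equal(st$specificity, 0)
  expect_equal(st$balanced_accuracy, 0.5)
  expect_equal(st$prevalence, 0.9)
})

test_that("zero-denominator metrics are NA, never 0 or 1", {
  preds <- make_preds(c("a", "b", "c"), full_auc = 0, subset_auc_med = 0)
  st <- cluster_confusion(preds, assign_clusters(preds$chem_id, rep(1, 3)))$stats
  expect_equal(st$specificity, 1)
  expect_true(is.na(st$sensitivity))
  expect_true(is.na(st$ppv))
  expect_true(is.na(st$balanced_accuracy)) # one undefined component -> NA
  expect_equal(st$prevalence, 0)
})

test_that("cluster statistics equal a brute-force per-chemical recount", {
  set.seed(17)
  n <- 60
  preds <- make_preds(sprintf("x%03d", 1:n),
                      full_auc = round(runif(n), 3),
                      subset_auc_med = round(runif(n), 3),
                      n_active_assays = sample(0:4, n, replace = TRUE))
  cl <- sample(1:8, n, replace = TRUE)
  assign <- assign_clusters(preds$chem_id, cl)
  res <- cluster_confusion(preds, assign, min_cluster_n = 2)

  for (i in seq_len(nrow(res$stats))) {
    row <- res$stats[i, ]
    p <- preds[cl == row$cluster_id, ]
    # independent recount straight from the call definitions
    tp <- sum(p$full_call == 1 & p$subset_call == 1)
    fp <- sum(p$full_call == 0 & p$subset_call == 1)
    tn <- sum(p$full_call == 0 & p$subset_call == 0)
    fn <- sum(p$full_call == 1 & p$subset_call == 0)
    expect_equal(unlist(row[c("tp", "fp", "tn", "fn")]),
                 c(tp = tp, fp = fp, tn = tn, fn = fn))
    expect_equal(row$accuracy, (tp + tn) / nrow(p))
    if (tp + fn > 0) expect_equal(row$sensitivity, tp / (tp + fn))
    if (tn + fp > 0) expect_equal(row$specificity, tn / (tn + fp))
    if (tp + fp > 0) expect_equal(row$ppv, tp / (tp + fp))
    if (tn + fn > 0) expect_equal(row$npv, tn / (tn + fn))
    expect_equal(row$mean_auc_diff, mean(p$subset_auc_med - p$full_auc))
    expect_equal(row$sd_auc_diff, sd(p$subset_auc_med - p$full_auc))
  }

  # conservation: scored clusters plus below-floor chemicals = global counts
  glob <- global_discrepancy_table(preds)
  got <- colSums(res$stats[, c("tp", "fp", "tn", "fn")]) +
    vapply(c("TP", "FP", "TN", "FN"),
           function(lab) sum(res$below_floor$confusion == lab), integer(1))
  expect_equal(unname(got), unname(glob$counts))

  # every predicted chemical needs a cluster
  expect_error(cluster_confusion(preds, assign_clusters("x001", 1)), "without a cluster")
})

test_that("prevalence partition splits clusters into all-negative, mixed and all-positive groups", {
  preds <- make_preds(
    sprintf("p%02d", 1:9),
    full_auc       = c(0,   0,   0,   0,    0.5, 0,   0.5, 0.5, 0.5),
    subset_auc_med = c(0,   0,   0,   0.3,  0.5, 0,   0.5, 0.5, 0.5))
  #                 |all-TN pair |FP+TN pair  |mixed pair |all-TP pair + spare TP
  assign <- assign_clusters(preds$chem_id, c(1, 1, 2, 2, 3, 3, 4, 4, 4))
  part <- partition_by_prevalence(cluster_confusion(preds, assign))
  expect_equal(part$n_clusters[part$group == "prevalence_0"], 2L)
  expect_equal(part$n_clusters[part$group == "prevalence_0_perfect"], 1L)
  expect_equal(part$n_clusters[part$group == "prevalence_0_with_fp"], 1L)
  expect_equal(part$n_clusters[part$group == "mixed"], 1L)
  expect_equal(part$n_clusters[part$group == "prevalence_1"], 1L)
  expect_equal(part$n_chemicals[part$group == "prevalence_1"], 3L)
  expect_equal(attr(part, "fp_chemicals_in_prev0"), 1L)
})

test_that("global discrepancy table reports counts, FP medians and the FN list", {
  # hand-built six-chemical set with two FPs: medians are the sorted middles
  preds <- make_preds(letters[1:6],
                      full_auc       = c(0.5, 0.5, 0,    0,    0,   0.3),
                      subset_auc_med = c(0.5, 0.5, 0.12, 0.18, 0,   0.05))
  g <- global_discrepancy_table(preds)
  expect_equal(unname(g$counts), c(2L, 2L, 1L, 1L))
  expect_equal(g$n_discrepant, 3L)
  expect_equal(g$fp_median_subset_auc, median(c(0.12, 0.18)))
  expect_equal(g$fp_median_full_auc, 0)
  expect_equal(g$false_negatives$chem_id, "f")
  expect_equal(g$false_negatives$full_auc, 0.3)

  # no discrepancies: zero counts and NA medians
  clean <- make_preds(c("x", "y"), full_auc = c(0.5, 0), subset_auc_med = c(0.5, 0))
  g2 <- global_discrepancy_table(clean)
  expect_equal(unname(g2$counts[c("FP", "FN")]), c(0L, 0L))
  expect_true(is.na(g2$fp_median_subset_auc))
})

test_that("a subset model identical to the full model is perfectly concordant per cluster", {
  set.seed(5)
  n <- 30
  auc <- round(runif(n), 3)
  preds <- make_preds(sprintf("s%02d", 1:n), full_auc = auc, subset_auc_med = auc)
  assign <- assign_clusters(preds$chem_id, rep(1:5, each = 6))
  st <- cluster_confusion(preds, assign)$stats
  expect_true(all(st$accuracy == 1))
  expect_true(all(st$mean_auc_diff == 0))
  expect_true(all(st$fp == 0 & st$fn == 0))
})

test_that("balanced accuracy equals accuracy for a balanced cluster with symmetric errors", {
  # prevalence 0.5, one error of each kind: accuracy = balanced accuracy = 2/3
  preds <- make_preds(sprintf("b%d", 1:6),
                      full_auc       = c(0.5, 0.5, 0.5, 0, 0, 0),
                      subset_auc_med = c(0.5, 0.5, 0,   0, 0, 0.5))
  st <- cluster_confusion(preds, assign_clusters(preds$chem_id, rep(1, 6)))$stats
  expect_equal(st$prevalence, 0.5)
  expect_equal(st$accuracy, st$balanced_accuracy)
  expect_equal(st$accuracy, 2 / 3)
})
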