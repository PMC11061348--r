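spec4 <- model_spec(paste0("a", 1:4))

test_that("subset score is the weighted mean of the model's assay AUCs", {
  expect_equal(subset_auc(c(0.2, 0.2, 0.2, 0.2), spec4), 0.2)
  expect_equal(subset_auc(c(0, 0, 0, 0), spec4), 0)
  w <- model_spec(paste0("a", 1:4), weights = c(2, 1, 1, 0))
  # (2*0.4 + 0.1 + 0.1 + 0) / 4 = 0.25
  expect_equal(subset_auc(c(0.4, 0.1, 0.1, 0.3), w), 0.25)
  # raw weighted sum when normalization is off
  wraw <- model_spec(paste0("a", 1:4), weights = c(2, 1, 1, 0), normalize_weights = FALSE)
  expect_equal(subset_auc(c(0.4, 0.1, 0.1, 0.3), wraw), 1)
  # named vectors are matched by assay, order-independently
  expect_equal(subset_auc(c(a4 = 0.3, a1 = 0.4, a2 = 0.1, a3 = 0.1), w), 0.25)
  expect_error(subset_auc(c(a1 = 0.4, a2 = 0.1, a3 = 0.1), w), "a4")
  expect_error(subset_auc(c(0.4, NA, 0.1, 0.3), spec4), "missing assay")
})

test_that("activity calls use a closed threshold; borderline scores stay negative", {
  expect_equal(dichotomize(0.1), 1L)     # exactly at threshold: active
  expect_equal(dichotomize(0.0976), 0L)  # borderline negative
  expect_equal(dichotomize(0.0901), 0L)
  expect_equal(dichotomize(c(0, 0.5, 1)), c(0L, 1L, 1L))
  expect_error(dichotomize(1.2), "\\[0, 1\\]")
})

test_that("active-assay counting is strictly greater than the floor", {
  expect_equal(count_active_assays(c(0, 0, 0, 0)), 0L)
  expect_equal(count_active_assays(c(0.5, 0, 0.001, 0)), 2L)
  expect_equal(count_active_assays(c(0.05, 0.2, 0.3, 0.4), floor = 0.05), 3L)
})

test_that("confusion labels follow the (full, subset) call convention", {
  expect_equal(label_confusion(1, 1), "TP")
  expect_equal(label_confusion(0, 1), "FP")
  expect_equal(label_confusion(1, 0), "FN")
  expect_equal(label_confusion(0, 0), "TN")
  expect_equal(label_confusion(c(1, 0), c(1, 1)), c("TP", "FP"))
})

test_that("subset score is monotone in each assay and constant under equal AUCs", {
  set.seed(8)
  for (rep in 1:20) {
    w <- runif(4)
    spec <- model_spec(paste0("a", 1:4), weights = w)
    x <- runif(4)
    base <- subset_auc(x, spec)
    i <- sample(4, 1)
    x2 <- x; x2[i] <- min(1, x[i] + runif(1, 0, 1 - x[i]))
    expect_gte(subset_auc(x2, spec), base)
    # constant inputs give back the constant for any positive weights
    cc <- runif(1)
    expect_equal(subset_auc(rep(cc, 4), spec), cc)
  }
})

test_that("scoring a chemical set propagates CI bounds and excludes incomplete chemicals", {
  assays <- paste0("a", 1:4)
  med <- rbind(P = c(0.3, 0.3, 0.3, 0.3),   # subset 0.3, TP
               N = c(0, 0, 0, 0),            # TN
               Q = c(0.2, 0.1, 0, 0),        # subset 0.075 -> negative
               M = c(0.5, NA, 0.5, 0.5))     # incomplete: excluded
  colnames(med) <- assays
  lo <- pmax(med - 0.1, 0); hi <- pmin(med + 0.1, 1)
  aucs <- assay_auc_table(med, lo, hi)
  ref <- full_model_reference(data.frame(
    chem_id = c("P", "N", "Q", "M"), full_auc = c(0.4, 0, 0.3, 0.5),
    antagonist_flag = FALSE))
  expect_message(preds <- score_predictions(aucs, spec4, ref), "excluded 1")
  expect_equal(preds$chem_id, c("P", "N", "Q"))
  expect_equal(attr(preds, "excluded")$chem_id, "M")
  expect_equal(preds$subset_auc_med, c(0.3, 0, 0.075))
  # CI ordering is preserved through the linear score
  expect_true(all(preds$subset_auc_lo <= preds$subset_auc_med))
  expect_true(all(preds$subset_auc_med <= preds$subset_auc_hi))
  expect_equal(preds$subset_auc_lo[1], 0.2)
  expect_equal(preds$confusion, c("TP", "TN", "FN"))
  expect_equal(preds$n_active_assays, c(4L, 0L, 2L))
})
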