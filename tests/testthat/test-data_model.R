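test_that("chemical table ingestion validates, collapses duplicates, fills optional columns", {
  path <- withr::local_tempfile(fileext = ".csv")

  write.csv(data.frame(chem_id = c("A", "B", "C"), smiles = c("C", "CC", "CCC")),
            path, row.names = FALSE)
  chems <- load_chemicals(path)
  expect_s3_class(chems, "chemical_table")
  expect_equal(nrow(chems), 3L)
  expect_equal(chems$casrn, rep("", 3)) # absent optional column filled

  # duplicate identifier collapses to first occurrence, with a warning
  write.csv(data.frame(chem_id = c("A", "A", "B"), name = c("first", "second", "b")),
            path, row.names = FALSE)
  expect_warning(chems <- load_chemicals(path), "duplicate")
  expect_equal(nrow(chems), 2L)
  expect_equal(chems$name[chems$chem_id == "A"], "first")

  # lacking a smiles column is fine; lacking chem_id is not
  write.csv(data.frame(chem_id = "A"), path, row.names = FALSE)
  expect_equal(load_chemicals(path)$smiles, "")
  write.csv(data.frame(id = c("A", "B")), path, row.names = FALSE)
  expect_error(load_chemicals(path), "chem_id")
  writeLines("chem_id,name", path)
  expect_error(load_chemicals(path), "empty")
})

test_that("fingerprint ingestion enforces strict 0/1 values and preserves order", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(chem_id = c("X", "Y"), b1 = c(1, 0), b2 = c(0, 1),
                       b3 = c(1, 1), b4 = c(0, 0)),
            path, row.names = FALSE)
  fps <- load_fingerprints(path)
  expect_equal(dim(fps$bits), c(2L, 4L))
  expect_equal(fps$chem_ids, c("X", "Y"))
  expect_equal(unname(fps$bits["X", ]), c(1L, 0L, 1L, 0L))

  write.csv(data.frame(chem_id = c("X", "Y"), b1 = c(1, 2), b2 = c(0, 1)),
            path, row.names = FALSE)
  expect_error(load_fingerprints(path), "row 'Y', column 'b1'")
})

test_that("assay AUC table loader builds matrices and enforces bound ordering", {
  path <- withr::local_tempfile(fileext = ".csv")
  long <- data.frame(chem_id = rep(c("A", "B"), each = 2),
                     assay = rep(c("a1", "a2"), 2),
                     auc_med = c(0.5, 0.2, 0, 0.9),
                     auc_lo = c(0.4, 0.1, 0, 0.8),
                     auc_hi = c(0.6, 0.3, 0, 1))
  write.csv(long, path, row.names = FALSE)
  aucs <- load_assay_aucs(path)
  expect_equal(aucs$auc_med["B", "a2"], 0.9)
  expect_equal(aucs$auc_lo["A", "a1"], 0.4)

  bad <- long; bad$auc_lo[1] <- 0.55
  write.csv(bad, path, row.names = FALSE)
  expect_error(load_assay_aucs(path), "lo <= med <= hi")

  bad <- long; bad$auc_med[1] <- 1.2
  write.csv(bad, path, row.names = FALSE)
  expect_error(load_assay_aucs(path), "\\[0, 1\\]")
})

test_that("tables round-trip through CSV/YAML to full precision", {
  dir <- withr::local_tempdir()
  set.seed(3)
  fps <- random_fps(6, 20, seed = 3)
  write_fingerprints(fps, file.path(dir, "fp.csv"))
  expect_identical(load_fingerprints(file.path(dir, "fp.csv"))$bits, fps$bits)

  med <- matrix(round(runif(12), 9), 3, 4,
                dimnames = list(c("A", "B", "C"), paste0("a", 1:4)))
  aucs <- assay_auc_table(med, pmax(med - 0.05, 0), pmin(med + 0.05, 1))
  write_assay_aucs(aucs, file.path(dir, "auc.csv"))
  back <- load_assay_aucs(file.path(dir, "auc.csv"))
  expect_equal(back$auc_med[rownames(med), colnames(med)], med, tolerance = 1e-12)
  expect_equal(back$auc_lo[rownames(med), colnames(med)], aucs$auc_lo, tolerance = 1e-12)

  spec <- model_spec(paste0("a", 1:4), weights = c(2, 1, 1, 0.5),
                     activity_threshold = 0.1)
  write_model_spec(spec, file.path(dir, "spec.yaml"))
  expect_equal(load_model_spec(file.path(dir, "spec.yaml")), spec)

  ref <- full_model_reference(data.frame(chem_id = c("A", "B"),
                                         full_auc = c(0.123456789012, 0),
                                         antagonist_flag = c(TRUE, FALSE)))
  write_full_model(ref, file.path(dir, "ref.csv"))
  expect_equal(load_full_model(file.path(dir, "ref.csv"))$full_auc, ref$full_auc,
               tolerance = 1e-12)
})

test_that("join_datasets intersects sources, lists exclusions, never drops silently", {
  chems <- chemical_table(data.frame(
    chem_id = c("U1", "U2", "U3", "T1", "T2"),
    in_universe = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    in_tested_set = c(FALSE, TRUE, FALSE, TRUE, TRUE)))
  fps <- fp_from_bits(list(1:3, 2:4, 3:5, 1:2), 10,
                      chem_ids = c("U1", "U2", "U3", "T1")) # T2 has no fingerprint
  med <- matrix(0.2, 3, 2, dimnames = list(c("U2", "T1", "T2"), c("a1", "a2")))
  aucs <- assay_auc_table(med)
  ref <- full_model_reference(data.frame(chem_id = c("U2", "T1", "T2"),
                                         full_auc = 0.5, antagonist_flag = FALSE))

  expect_message(bundle <- join_datasets(chems, fps, aucs, ref), "universe 3")
  expect_setequal(bundle$universe_ids, c("U1", "U2", "U3"))
  expect_setequal(bundle$tested_ids, c("U2", "T1"))
  expect_equal(bundle$missing_fingerprint, "T2")
  # conservation: stored + excluded covers every tested chemical
  expect_setequal(c(bundle$tested_ids, bundle$missing_fingerprint),
                  chems$chem_id[chems$in_tested_set])

  # tested set fully inside the universe: overlap equals tested size
  chems2 <- chems; chems2$in_tested_set <- chems2$in_universe
  med2 <- matrix(0.2, 3, 2, dimnames = list(c("U1", "U2", "U3"), c("a1", "a2")))
  ref2 <- full_model_reference(data.frame(chem_id = c("U1", "U2", "U3"),
                                          full_auc = 0.5, antagonist_flag = FALSE))
  bundle2 <- suppressMessages(join_datasets(chems2, fps, assay_auc_table(med2), ref2))
  expect_equal(bundle2$counts[["n_overlap"]], bundle2$counts[["n_tested"]])

  # disjoint AUC table is a hard error
  med3 <- matrix(0.2, 1, 2, dimnames = list("Z9", c("a1", "a2")))
  expect_error(suppressMessages(join_datasets(chems, fps, assay_auc_table(med3), ref)),
               "no overlap")
})
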