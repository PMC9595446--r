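test_that("presets reproduce the published cohort shapes and imbalances", {
  presets <- preset_cohorts(seed = 1)
  shapes <- list(glioma = c(69, 160), prostate = c(57, 306),
                 dlbcl_center1 = c(44, 57), dlbcl_center2 = c(41, 57))
  imb <- list(glioma = "67-vs-33", prostate = "52-vs-48",
              dlbcl_center1 = "68-vs-32", dlbcl_center2 = "61-vs-39")
  for (nm in names(shapes)) {
    co <- generate_cohort(presets[[nm]])$cohort
    expect_equal(dim(co$X), shapes[[nm]], label = nm)
    ir <- imbalance_ratio(co)
    want <- as.integer(strsplit(imb[[nm]], "-vs-")[[1]])
    expect_lte(abs(ir$majority_pct - want[1]), 2, label = nm)
  }
  expect_equal(presets$dlbcl_center2$outlier_fraction, 0)
})

test_that("ground truth bookkeeping is exact", {
  gen <- generate_cohort(synthetic_spec(n_samples = 200, n_features = 20,
                                        n_informative = 5, n_redundant = 5,
                                        outlier_fraction = 0.05, seed = 2))
  expect_length(gen$ground_truth$outlier_ids, 10)
  # relocated rows really are extreme
  out_rows <- match(gen$ground_truth$outlier_ids, gen$cohort$sample_ids)
  expect_true(all(rowMeans(abs(gen$cohort$X[out_rows, ])) > 5))
  expect_true(all(gen$ground_truth$overlap_ids %in%
                    gen$cohort$sample_ids[gen$cohort$y == 1]))
  # reproducibility
  gen2 <- generate_cohort(synthetic_spec(n_samples = 200, n_features = 20,
                                         n_informative = 5, n_redundant = 5,
                                         outlier_fraction = 0.05, seed = 2))
  expect_identical(gen$cohort$X, gen2$cohort$X)
})

test_that("all presets generate across a seed sweep", {
  for (s in 1:10) {
    for (sp in preset_cohorts(seed = s)) {
      expect_s3_class(generate_cohort(sp)$cohort, "labeled_cohort")
    }
  }
})

test_that("impossible specs error", {
  expect_error(synthetic_spec(n_features = 5, n_informative = 4,
                              n_redundant = 3), "exceed")
  expect_error(synthetic_spec(n_samples = 10,
                              imbalance_minority_fraction = 0.05),
               "at least 2")
})

test_that("SFS recovers planted informative features", {
  hits <- vapply(1:10, function(s) {
    gen <- generate_cohort(synthetic_spec(n_samples = 80, n_features = 100,
                                          n_informative = 5, n_redundant = 0,
                                          class_separation = 1.5,
                                          imbalance_minority_fraction = 0.4,
                                          outlier_fraction = 0,
                                          borderline_overlap = 0, seed = s))
    sel <- fit_sfs_r2(gen$cohort)$step$state$selected  # registry default n_keep
    sum(sel %in% gen$ground_truth$informative_idx)
  }, numeric(1))
  expect_gte(mean(hits >= 3), 0.8)
})

test_that("diagnostic scores track their generator knobs monotonically", {
  out_frac <- c(0, 0.02, 0.05, 0.08, 0.12)
  out_means <- vapply(out_frac, function(fr) {
    mean(vapply(1:10, function(s) {
      co <- generate_cohort(synthetic_spec(n_samples = 80, n_features = 10,
                                           n_informative = 4, n_redundant = 3,
                                           outlier_fraction = fr,
                                           outlier_magnitude = 10,
                                           seed = s))$cohort
      outlier_score(co, seed = s)
    }, numeric(1)))
  }, numeric(1))
  expect_gt(cor(out_frac, out_means, method = "spearman"), 0.8)

  overlaps <- c(0, 0.2, 0.4, 0.6, 0.8)
  bl_means <- vapply(overlaps, function(bo) {
    mean(vapply(1:10, function(s) {
      co <- generate_cohort(synthetic_spec(n_samples = 80, n_features = 10,
                                           n_informative = 4, n_redundant = 3,
                                           class_separation = 2,
                                           borderline_overlap = bo,
                                           outlier_fraction = 0,
                                           seed = s))$cohort
      borderline_score(co)
    }, numeric(1)))
  }, numeric(1))
  expect_gt(cor(overlaps, bl_means, method = "spearman"), 0.8)
})

test_that("zero separation yields chance-level prediction", {
  gen <- generate_cohort(synthetic_spec(n_samples = 80, n_features = 10,
                                        n_informative = 4, n_redundant = 3,
                                        class_separation = 0,
                                        imbalance_minority_fraction = 0.5,
                                        outlier_fraction = 0, seed = 33))
  co <- gen$cohort
  aucs <- vapply(1:15, function(i) {
    sp <- stratified_split_for_test(co$y, 0.8, i)
    m <- train_classifier(classifier_spec("RF", seed = 3),
                          labeled_cohort(co$X[sp$train, ], co$y[sp$train]))
    auc_rank(predict_scores(m, co$X[sp$validation, , drop = FALSE]),
             co$y[sp$validation])
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.12)
})
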