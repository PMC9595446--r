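test_that("make_splits: sizes, disjointness, stratification, determinism", {
  co <- random_cohort(n = 10, p = 2, seed = 1, minority_fraction = 0.4)
  sp <- make_splits(co, split_plan(folds = 3, seed = 2))
  for (s in sp) {
    expect_equal(length(s$train), 8)
    expect_equal(length(s$validation), 2)
    expect_length(intersect(s$train, s$validation), 0)
    expect_setequal(c(s$train, s$validation), 1:10)
  }
  y <- rep(c(1, 0), c(9, 21))  # 30%/70%
  co2 <- make_cohort(matrix(rnorm(60), 30, 2), y)
  sp2 <- make_splits(co2, split_plan(folds = 50, seed = 3))
  fr <- vapply(sp2, function(s) mean(y[s$train] == 1), numeric(1))
  expect_true(all(abs(fr * 24 - 0.3 * 24) <= 1))  # within one sample
  expect_identical(make_splits(co2, split_plan(folds = 5, seed = 9)),
                   make_splits(co2, split_plan(folds = 5, seed = 9)))
  tiny <- random_cohort(n = 9, p = 2, seed = 1)
  expect_error(make_splits(tiny, split_plan()), "n >= 10")
})

test_that("confusion metrics follow their definitions and flag zero denominators", {
  m <- confusion_metrics(TP = 3, FP = 1, TN = 5, FN = 1)
  expect_equal(m[["ACC"]], 0.8)
  expect_equal(m[["SNS"]], 0.75)
  expect_equal(m[["SPC"]], 5 / 6, tolerance = 1e-12)
  expect_equal(m[["PPV"]], 0.75)
  expect_equal(m[["NPV"]], 5 / 6, tolerance = 1e-12)
  perfect <- confusion_metrics(TP = 4, FP = 0, TN = 6, FN = 0)
  expect_equal(unname(perfect), rep(1, 5))
  nospc <- confusion_metrics(TP = 2, FP = 0, TN = 0, FN = 1)
  expect_true(is.na(nospc[["SPC"]]))
  expect_false(is.na(nospc[["SNS"]]))
  expect_error(confusion_metrics(-1, 0, 0, 0), "non-negative")
})

test_that("rank AUC: perfect, tied, and oracle-equivalent on random draws", {
  expect_equal(auc_rank(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc_rank(rep(0.3, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(auc_rank(c(0.1, 0.2), c(1, 1)), "both classes")
  set.seed(4)
  for (i in 1:20) {
    n <- sample(8:25, 1)
    y <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    s <- round(runif(n), 2)  # rounding forces ties
    expect_equal(auc_rank(s, y), oracle_auc(s, y), tolerance = 1e-12)
  }
})

test_that("two-group ANOVA equals t^2 and degenerates to p=1 on zero variance", {
  same <- c(0.5, 0.5, 0.5)
  p <- anova_p(same, same)
  expect_equal(as.numeric(p), 1)
  expect_identical(attr(p, "flag"), "zero-variance")
  set.seed(5)
  for (i in 1:50) {
    a <- rnorm(sample(5:30, 1), mean = runif(1))
    b <- rnorm(sample(5:30, 1))
    expect_equal(as.numeric(anova_p(a, b)),
                 t.test(a, b, var.equal = TRUE)$p.value, tolerance = 1e-12)
  }
  set.seed(6)
  expect_lt(as.numeric(anova_p(rnorm(100, 0.7, 0.01), rnorm(100, 0.9, 0.01))),
            0.001)
})

test_that("ci95 is t-based with the expected large-n half-width", {
  expect_equal(unname(ci95(rep(0.7, 5))), c(0.7, 0.7))
  set.seed(7)
  v <- rnorm(40, 0.6, 0.1)
  ci <- ci95(v)
  expect_gt(mean(v), ci[["low"]])
  expect_lt(mean(v), ci[["high"]])
  big <- rnorm(1e4)
  half <- diff(ci95(big)) / 2
  expect_equal(unname(half), 1.96 * sd(big) / 100, tolerance = 0.01)
})

test_that("the manual baseline is the fixed FS + SMOTE pipeline", {
  mp <- manual_pipeline()
  expect_equal(pipeline_methods(mp), c("SFS", "SMOTE"))
  expect_true(is_valid_pipeline(mp, default_restrictions()))
  expect_identical(format(manual_pipeline()), format(mp))
})

test_that("run_experiment produces coherent fold metrics and summaries", {
  gen <- generate_cohort(synthetic_spec(n_samples = 50, n_features = 10,
                                        n_informative = 4, n_redundant = 2,
                                        imbalance_minority_fraction = 0.35,
                                        seed = 23))
  rep_ <- suppressWarnings(run_experiment(
    gen$cohort, plan = split_plan(folds = 3, seed = 8),
    config = search_config(population_size = 5, generations = 2,
                           inner_splits = 2, surrogate_trees = 25,
                           elitism_count = 1, seed = 8),
    schemes = c("RF", "MG"), arms = c("none", "mldp", "manual")))
  m <- rep_$metrics
  expect_equal(nrow(m), 3 * 2 * 3)  # folds x schemes x arms
  expect_true(all(m$AUC >= 0 & m$AUC <= 1, na.rm = TRUE))
  expect_setequal(unique(rep_$summary$metric),
                  c("ACC", "SNS", "SPC", "PPV", "NPV", "AUC"))
  expect_true(all(rep_$anova$p_value >= 0 & rep_$anova$p_value <= 1,
                  na.rm = TRUE))
  expect_true(all(rep_$occurrence >= 0 & rep_$occurrence <= 100))
  expect_length(rep_$pipelines, 3)
  # reproducibility of the whole report
  rep2 <- suppressWarnings(run_experiment(
    gen$cohort, plan = split_plan(folds = 3, seed = 8),
    config = search_config(population_size = 5, generations = 2,
                           inner_splits = 2, surrogate_trees = 25,
                           elitism_count = 1, seed = 8),
    schemes = c("RF", "MG"), arms = c("none", "mldp", "manual")))
  expect_identical(rep_$metrics, rep2$metrics)
})

test_that("dual-center mode: one fold, binary occurrences, invariant val counts", {
  presets <- preset_cohorts(seed = 5)
  c1 <- generate_cohort(presets$dlbcl_center1)$cohort
  c2 <- generate_cohort(presets$dlbcl_center2)$cohort
  rep_ <- suppressWarnings(run_experiment(
    c1, plan = split_plan(mode = "dual_center", seed = 4),
    config = search_config(population_size = 5, generations = 2,
                           inner_splits = 2, surrogate_trees = 25,
                           elitism_count = 1, seed = 4),
    schemes = "RF", arms = c("none", "mldp"),
    validation_cohort = c2))
  expect_equal(rep_$plan$folds, 1)
  expect_true(all(rep_$occurrence %in% c(0, 100)))
  expect_equal(nrow(rep_$metrics), 2)  # 1 fold x 1 scheme x 2 arms
})
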