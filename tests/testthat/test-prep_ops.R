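test_that("isolation forest removes a planted extreme point and nothing else matters", {
  set.seed(2)
  X <- rbind(matrix(rnorm(100), 50, 2), c(100, 100))
  co <- make_cohort(X, c(rep(0, 26), rep(1, 25)))
  res <- fit_apply_isolation_forest(co, score_threshold = 0.6, seed = 7)
  expect_equal(which.max(res$scores), 51)  # planted point attains max score
  expect_false("s51" %in% res$cohort$sample_ids)
  expect_equal(nrow(res$cohort$X), 50)
  # retained rows are an unmodified subset of the input
  expect_equal(res$cohort$X, co$X[match(res$cohort$sample_ids, co$sample_ids), ],
               ignore_attr = TRUE)
})

test_that("isolation forest respects the score bound and small-n guard", {
  co <- random_cohort(n = 30, p = 3, seed = 5)
  res <- fit_apply_isolation_forest(co, score_threshold = 1.0, seed = 1)
  expect_equal(nrow(res$cohort$X), 30)  # score <= 1 always
  expect_true(all(res$scores > 0 & res$scores <= 1))
  tiny <- random_cohort(n = 7, p = 2, seed = 1, minority_fraction = 0.45)
  expect_error(fit_apply_isolation_forest(tiny), "too few samples")
})

test_that("SFS picks a perfect predictor first with R^2 = 1", {
  set.seed(3)
  X <- matrix(rnorm(30 * 11), 30, 11)
  y <- as.integer(X[, 3] > 0)
  X[, 3] <- y  # feature 3 IS the label
  co <- make_cohort(X, y)
  res <- fit_sfs_r2(co, n_keep = 3)
  expect_equal(res$step$state$selected[1], 3)
  expect_equal(res$step$state$r2_trace[1], 1.0, tolerance = 1e-10)
  expect_error(fit_sfs_r2(co, n_keep = 0), "n_keep")
})

test_that("SFS greedy trace matches the brute-force oracle", {
  set.seed(4)
  X <- matrix(rnorm(40 * 5), 40, 5)
  y <- as.integer(0.8 * X[, 2] + 0.5 * X[, 5] + rnorm(40, sd = 0.7) > 0)
  co <- make_cohort(X, y)
  res <- fit_sfs_r2(co, n_keep = 2, tol = 0)
  # first pick: argmax of single-feature R^2 by brute force
  r2_single <- vapply(1:5, function(j) oracle_r2(X[, j], y), numeric(1))
  expect_equal(res$step$state$selected[1], which.max(r2_single))
  # second pick: brute force over remaining features given the first
  j1 <- res$step$state$selected[1]
  r2_pair <- vapply(setdiff(1:5, j1), function(j) {
    f <- lm(y ~ X[, j1] + X[, j])
    1 - sum(residuals(f)^2) / sum((y - mean(y))^2)
  }, numeric(1))
  expect_equal(res$step$state$selected[2],
               setdiff(1:5, j1)[which.max(r2_pair)])
  # validation transform is a column subset
  expect_equal(apply_fitted_step(res$step, co$X), res$cohort$X,
               ignore_attr = TRUE)
})

test_that("PCA matches a dense eigendecomposition and handles rank-1 input", {
  set.seed(5)
  x <- rnorm(20)
  co1 <- make_cohort(cbind(x, 2 * x), rep(c(0, 1), 10))
  res1 <- fit_pca(co1, variance_retained = 0.9)
  expect_equal(res1$step$state$n_components, 1)

  X <- matrix(rnorm(25 * 3), 25, 3)
  co <- make_cohort(X, rep(c(0, 1), c(12, 13)))
  res <- fit_pca(co, variance_retained = 1.0)
  ev_oracle <- sort(eigen(cov(X))$values, decreasing = TRUE)
  expect_equal(res$step$state$eigenvalues, ev_oracle, tolerance = 1e-10)
  expect_equal(res$step$state$n_components, qr(scale(X, scale = FALSE))$rank)
  expect_error(fit_pca(co, variance_retained = 1.3), "variance_retained")
  # projection of training data reproduces the fitted scores
  expect_equal(apply_fitted_step(res$step, co$X), res$cohort$X,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("random over/undersampling hit their target ratios exactly", {
  co <- make_cohort(matrix(rnorm(20), 10, 2), rep(c(1, 0), c(2, 8)))
  ro <- suppressWarnings(apply_random_oversample(co, 1.0, seed = 3))
  expect_equal(as.vector(table(ro$cohort$y)), c(8, 8))
  added <- setdiff(ro$cohort$sample_ids, co$sample_ids)
  for (id in added) {
    row <- ro$cohort$X[ro$cohort$sample_ids == id, ]
    src <- sub("_dup[0-9]+$", "", id)
    expect_equal(row, co$X[co$sample_ids == src, ], ignore_attr = TRUE)
  }
  ru <- apply_random_undersample(co, 1.0, seed = 3)
  expect_equal(as.vector(table(ru$cohort$y)), c(2, 2))
  expect_true(all(ru$cohort$sample_ids %in% co$sample_ids))
  expect_true(all(co$sample_ids[co$y == 1] %in% ru$cohort$sample_ids))
  # at-or-below-current target is a warned no-op
  expect_warning(apply_random_oversample(co, 0.25, seed = 1), "no-op")
})

test_that("resampling operators are bit-reproducible under a fixed seed", {
  co <- random_cohort(n = 30, p = 4, seed = 8, minority_fraction = 0.3)
  for (f in list(function(s) apply_random_oversample(co, 1, s)$cohort$X,
                 function(s) apply_random_undersample(co, 1, s)$cohort$X,
                 function(s) apply_smote(co, 3, 1, s)$cohort$X)) {
    expect_identical(f(42), f(42))
  }
})

test_that("SMOTE interpolates inside the minority segment", {
  X <- rbind(c(0, 0), c(1, 1), matrix(rnorm(16, 10), 8, 2))
  co <- make_cohort(X, rep(c(1, 0), c(2, 8)))
  res <- apply_smote(co, k_neighbors = 1, target_ratio = 1.0, seed = 2)
  synth <- res$cohort$X[grepl("^synth", res$cohort$sample_ids), , drop = FALSE]
  expect_equal(nrow(synth), 6)
  expect_equal(synth[, 1], synth[, 2], tolerance = 1e-12)  # on the segment (t, t)
  expect_true(all(synth >= 0 & synth <= 1))
})

test_that("SMOTE synthetic points stay in the minority convex hull (per-feature box)", {
  co <- random_cohort(n = 30, p = 3, seed = 13, minority_fraction = 0.25)
  res <- apply_smote(co, k_neighbors = 3, target_ratio = 1.0, seed = 5)
  synth <- res$cohort$X[grepl("^synth", res$cohort$sample_ids), , drop = FALSE]
  minX <- co$X[co$y == 1, , drop = FALSE]
  for (j in seq_len(ncol(minX))) {
    expect_true(all(synth[, j] >= min(minX[, j]) - 1e-12))
    expect_true(all(synth[, j] <= max(minX[, j]) + 1e-12))
  }
  # 3 minority / 9 majority at target 1.0 adds exactly 6 rows
  co2 <- make_cohort(matrix(rnorm(24), 12, 2), rep(c(1, 0), c(3, 9)))
  res2 <- apply_smote(co2, k_neighbors = 2, target_ratio = 1.0, seed = 1)
  expect_equal(nrow(res2$cohort$X), 18)
})

test_that("borderline SMOTE triages danger membership like the brute-force m-NN oracle", {
  # overlapping 1-D classes
  set.seed(21)
  x <- c(rnorm(10, 0), rnorm(20, 1.2))
  co <- make_cohort(cbind(x), rep(c(1, 0), c(10, 20)))
  m <- 5
  Xz <- oracle_zscore(co$X)
  D <- as.matrix(dist(Xz)); diag(D) <- Inf
  oracle_class <- vapply(which(co$y == 1), function(i) {
    nb <- order(D[i, ])[1:m]
    n_maj <- sum(co$y[nb] == 0)
    if (n_maj == m) "noise" else if (n_maj >= m / 2) "danger" else "safe"
  }, character(1))
  sets <- mldprep:::bsmote_danger_sets(Xz, co$y, 1L, m)
  expect_setequal(sets$danger, which(co$y == 1)[oracle_class == "danger"])
  expect_setequal(sets$noise, which(co$y == 1)[oracle_class == "noise"])
})

test_that("borderline SMOTE is a no-op on well-separated classes", {
  X <- rbind(matrix(rnorm(10, 0, 0.1), 5, 2), matrix(rnorm(30, 50, 0.1), 15, 2))
  co <- make_cohort(X, rep(c(1, 0), c(5, 15)))
  expect_warning(res <- apply_borderline_smote(co, k_neighbors = 2,
                                               m_danger = 4, seed = 1),
                 "empty danger set")
  expect_equal(res$cohort$X, co$X)
})

test_that("Tomek links match brute force and removal targets the majority member", {
  co <- make_cohort(cbind(c(0.0, 0.1, 5.0)), c(1, 0, 0))
  links <- tomek_links(co)
  expect_equal(unname(links), matrix(c(1, 2), 1))
  res <- apply_tomek_links(co)
  expect_equal(res$cohort$sample_ids, c("s1", "s3"))  # majority member 0.1 removed

  # separation limit: identity
  far <- make_cohort(cbind(c(0, 0.2, 50, 50.2)), c(1, 1, 0, 0))
  expect_equal(apply_tomek_links(far)$cohort$X, far$X)

  # random cohorts vs the quadratic oracle
  for (s in 1:10) {
    rc <- random_cohort(n = 20, p = 2, seed = s, minority_fraction = 0.35)
    expect_equal(unname(tomek_links(rc)), unname(oracle_tomek(rc)),
                 label = paste("seed", s))
  }
})

test_that("oversampling to target 1.0 yields a balanced cohort", {
  for (s in 1:3) {
    co <- random_cohort(n = 27, p = 3, seed = s, minority_fraction = 0.3)
    for (f in list(apply_random_oversample, apply_smote)) {
      out <- suppressWarnings(f(co, target_ratio = 1.0, seed = s))$cohort
      ir <- imbalance_ratio(out)
      expect_lte(ir$majority_pct_exact - ir$minority_pct_exact, 100 / nrow(out$X) + 1e-9)
    }
  }
})

test_that("sample-space steps refuse application to unseen data", {
  co <- random_cohort(n = 20, p = 3, seed = 2)
  st <- suppressWarnings(apply_smote(co, 2, 1, 1))$step
  expect_error(apply_fitted_step(st, co$X), "sample space")
})

test_that("fit_pipeline chains steps and transform_features replays feature space only", {
  gen <- generate_cohort(synthetic_spec(n_samples = 60, n_features = 12,
                                        n_informative = 4, n_redundant = 3,
                                        imbalance_minority_fraction = 0.3,
                                        seed = 6))
  co <- gen$cohort
  pl <- pipeline("IF", prep_step("SFS", list(n_keep = 4)), "SMOTE")
  fp <- suppressWarnings(fit_pipeline(pl, co, seed = 9))
  expect_s3_class(fp, "mldp_fitted_pipeline")
  expect_equal(ncol(fp$cohort$X), 4)
  ir <- imbalance_ratio(fp$cohort)
  expect_lte(ir$majority_pct - ir$minority_pct, 4)
  Xv <- transform_features(fp, co$X[1:7, , drop = FALSE])
  expect_equal(nrow(Xv), 7)   # sample count invariant
  expect_equal(ncol(Xv), 4)
})
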