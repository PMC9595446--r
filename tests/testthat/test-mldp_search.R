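test_that("roc_distance matches hand arithmetic and its bounds", {
  expect_equal(roc_distance(1, 1), 0)
  expect_equal(roc_distance(0, 0), sqrt(2))
  expect_equal(roc_distance(0.6, 0.8), sqrt(0.16 + 0.04))
  expect_error(roc_distance(1.2, 0.5), "\\[0, 1\\]")
})

test_that("fitness is near zero on separable data and poor on permuted labels", {
  set.seed(2)
  y <- rep(c(0L, 1L), each = 25)
  X <- matrix(rnorm(100, sd = 0.3), 50, 2) + 4 * y
  co <- make_cohort(X, y)
  cfg <- test_search_config(seed = 3)
  rec <- evaluate_fitness(pipeline(), co, cfg)
  expect_lt(rec$fitness, 0.15)
  expect_true(all(rec$per_split$distance >= 0 &
                    rec$per_split$distance <= sqrt(2)))

  set.seed(4)
  co_perm <- make_cohort(matrix(rnorm(100), 50, 2), sample(y))
  rec_p <- evaluate_fitness(pipeline(), co_perm, cfg)
  expect_gt(rec_p$fitness, 0.5)
})

test_that("fitness caching returns identical records", {
  co <- random_cohort(n = 30, p = 4, seed = 5, minority_fraction = 0.35)
  cfg <- test_search_config(seed = 6)
  cache <- new.env()
  pl <- pipeline("IF", "SMOTE")
  r1 <- suppressWarnings(evaluate_fitness(pl, co, cfg, cache = cache))
  r2 <- evaluate_fitness(pl, co, cfg, cache = cache)
  expect_false(r1$cached)
  expect_true(r2$cached)
  expect_identical(r1$fitness, r2$fitness)
})

test_that("a class-destroying pipeline gets worst fitness, not an error", {
  # undersampling a 2-vs-28 cohort after IF at a punishing threshold can
  # degenerate; the guard converts failures to sqrt(2)
  co <- make_cohort(rbind(matrix(rnorm(56), 28, 2),
                          matrix(rnorm(4, 8), 2, 2)),
                    rep(c(0L, 1L), c(28, 2)))
  cfg <- test_search_config(seed = 7)
  rec <- suppressWarnings(
    evaluate_fitness(pipeline(prep_step("SMOTE", list(k_neighbors = 5))),
                     co, cfg))
  expect_true(is.finite(rec$fitness))
  expect_lte(rec$fitness, sqrt(2) + 1e-12)
})

test_that("tournament selection prefers fitter pipelines and is reproducible", {
  pop <- lapply(1:6, function(i) {
    structure(list(pipeline = do.call(pipeline, as.list(
      mldp_methods()$method[seq_len(i)])), fitness = i / 10),
      class = "fitness_record")
  })
  p_same <- select_parents(pop, seed = 3)
  expect_identical(format(p_same[[1]]$pipeline),
                   format(select_parents(pop, seed = 3)[[1]]$pipeline))
  lens <- vapply(1:2000, function(i) {
    length(select_parents(pop, seed = i)[[1]]$pipeline)
  }, numeric(1))
  picks <- table(factor(lens, levels = 1:6))
  expect_gt(picks[["1"]], picks[["6"]])  # best picked far more than worst

  two <- pop[1:2]
  pr <- select_parents(two, seed = 1)
  expect_setequal(c(format(pr[[1]]$pipeline), format(pr[[2]]$pipeline)),
                  c(format(two[[1]]$pipeline), format(two[[2]]$pipeline)))
  expect_error(select_parents(pop[1], seed = 1), "at least 2")
})

test_that("crossover follows the pinned cut example and degenerate case", {
  p1 <- pipeline("IF", "SFS")
  p2 <- pipeline("SMOTE", "TL")
  child <- make_offspring(p1, p2, cuts = c(1, 0))
  expect_equal(pipeline_methods(child), c("IF", "SMOTE", "TL"))

  p <- pipeline("IF")
  same <- make_offspring(p, p, rates = list(crossover = 0, mutation = 0,
                                            hyper = 0), seed = 5)
  expect_equal(pipeline_methods(same), "IF")
})

test_that("offspring always satisfy the restrictions (property sweep)", {
  rt <- default_restrictions()
  tree <- build_pipeline_tree(rt)
  bad <- 0
  for (i in 1:400) {
    p1 <- sample_pipeline(tree, seed = 2 * i)
    p2 <- sample_pipeline(tree, seed = 2 * i + 1)
    child <- make_offspring(p1, p2, rt, seed = 10000 + i)
    if (!is_valid_pipeline(child, rt)) bad <- bad + 1
  }
  expect_equal(bad, 0)
})

test_that("hyperparameter mutation stays inside registry bounds", {
  reg <- hyperparam_registry()
  set.seed(8)
  for (i in 1:50) {
    pl <- pipeline("SMOTE", "IF")
    mut <- mldprep:::mutate_hyperparams(pl)
    for (st in unclass(mut)) {
      for (nm in names(st$hyperparams)) {
        spec <- reg[[st$method]][[nm]]
        expect_gte(st$hyperparams[[nm]], spec$lower)
        expect_lte(st$hyperparams[[nm]], spec$upper)
      }
    }
  }
})

test_that("run_mldp: monotone best fitness, bounded audit, reproducibility", {
  gen <- generate_cohort(synthetic_spec(n_samples = 50, n_features = 10,
                                        n_informative = 4, n_redundant = 2,
                                        imbalance_minority_fraction = 0.35,
                                        outlier_fraction = 0.04, seed = 16))
  co <- gen$cohort
  cfg <- search_config(population_size = 6, generations = 3,
                       plateau_patience = 3, inner_splits = 2,
                       surrogate_trees = 30, seed = 17)
  res <- suppressWarnings(run_mldp(co, config = cfg))
  expect_true(all(diff(res$trace$best_fitness) <= 1e-12))
  expect_true(all(res$audit_ids %in% co$sample_ids))
  expect_gte(res$best_fitness, 0)
  expect_lte(res$best_fitness, sqrt(2))
  expect_true(is_valid_pipeline(res$best_pipeline, default_restrictions()))

  res2 <- suppressWarnings(run_mldp(co, config = cfg))
  expect_identical(res$best_fitness, res2$best_fitness)
  expect_identical(format(res$best_pipeline), format(res2$best_pipeline))
})
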