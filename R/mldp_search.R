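#' Evolutionary-search configuration
#'
#' The originating study did not publish its evolutionary settings, so all
#' defaults here are this package's declared conventions: a modest budget
#' that converges on the synthetic cohorts in minutes, with every knob
#' exposed.
#'
#' @param population_size pipelines per generation.
#' @param generations maximum generations.
#' @param plateau_patience stop after this many generations without
#'   best-fitness improvement.
#' @param crossover_rate,mutation_rate,hyperparam_mutation_rate probabilities
#'   of one-point crossover, one structural mutation and one hyperparameter
#'   perturbation per offspring.
#' @param elitism_count best pipelines carried over unchanged.
#' @param tournament_size tournament size for parent selection.
#' @param inner_splits,inner_split_ratio internal stratified
#'   training-only splits used by the fitness; ratio in `(0.5, 0.95)`.
#' @param surrogate classifier scheme id used as fitness surrogate.
#' @param surrogate_trees tree count of the RF surrogate (budget knob).
#' @param include_empty whether the empty pipeline is in the searchable space.
#' @param seed base seed; all internal randomness derives from it.
#' @return object of class `search_config`.
#' @export
search_config <- function(population_size = 24, generations = 20,
                          plateau_patience = 5, crossover_rate = 0.9,
                          mutation_rate = 0.3, hyperparam_mutation_rate = 0.3,
                          elitism_count = 2, tournament_size = 3,
                          inner_splits = 5, inner_split_ratio = 0.8,
                          surrogate = "RF", surrogate_trees = 100,
                          include_empty = TRUE, seed = 1) {
  rates <- c(crossover_rate, mutation_rate, hyperparam_mutation_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (elitism_count >= population_size) {
    stop("elitism_count must be smaller than population_size")
  }
  if (inner_split_ratio <= 0.5 || inner_split_ratio >= 0.95) {
    stop("inner_split_ratio must lie in (0.5, 0.95)")
  }
  structure(list(population_size = population_size, generations = generations,
                 plateau_patience = plateau_patience,
                 crossover_rate = crossover_rate, mutation_rate = mutation_rate,
                 hyperparam_mutation_rate = hyperparam_mutation_rate,
                 elitism_count = elitism_count, tournament_size = tournament_size,
                 inner_splits = inner_splits,
                 inner_split_ratio = inner_split_ratio,
                 surrogate = surrogate, surrogate_trees = surrogate_trees,
                 include_empty = include_empty, seed = as.integer(seed)),
            class = "search_config")
}

#' ROC distance of an operating point
#'
#' Euclidean distance of `(sensitivity, specificity)` from the perfect
#' corner `(1, 1)`: `sqrt((1 - sens)^2 + (1 - spec)^2)`. Lower is better;
#' bounded by `sqrt(2)`.
#'
#' @param sens,spec fractions in `[0, 1]`.
#' @return the distance.
#' @export
roc_distance <- function(sens, spec) {
  if (any(sens < 0 | sens > 1 | spec < 0 | spec > 1)) {
    stop("sens and spec must lie in [0, 1]")
  }
  sqrt((1 - sens)^2 + (1 - spec)^2)
}

new_audit <- function() {
  e <- new.env(parent = emptyenv())
  e$ids <- character(0)
  e
}

audit_touch <- function(audit, ids) {
  if (!is.null(audit)) audit$ids <- unique(c(audit$ids, ids))
}

#' Fitness of a pipeline on training data only
#'
#' For each of `inner_splits` stratified splits of the *training* cohort, the
#' full pipeline is fitted on the inner-train part, its feature-space steps
#' applied to the inner-validation part, a fixed-seed surrogate classifier
#' trained, scores thresholded at 0.5, and the ROC distance of the
#' resulting (sensitivity, specificity) recorded. The fixed-cutoff
#' operating point deliberately rewards pipelines that balance the two
#' error types (it is what makes imbalance-correction steps competitive in
#' the search); see the methods vignette for the trade-off against
#' ranking-quality criteria. Fitness is the mean distance over the splits; a
#' pipeline that empties a class receives the worst fitness `sqrt(2)` with a
#' warning instead of an error.
#'
#' @param pl an `mldp_pipeline`.
#' @param cohort training [labeled_cohort()].
#' @param config a [search_config()].
#' @param cache optional environment used as a fitness cache keyed by the
#'   pipeline signature.
#' @param audit optional audit environment recording every sample id touched.
#' @return list (class `fitness_record`) with `pipeline`, `fitness`,
#'   `per_split` (data.frame of sens/spec/distance), `cached`.
#' @export
evaluate_fitness <- function(pl, cohort, config = search_config(),
                             cache = NULL, audit = NULL) {
  check_training_cohort(cohort)
  audit_touch(audit, cohort$sample_ids)
  key <- pipeline_signature(pl)
  if (!is.null(cache) && !is.null(cache[[key]])) {
    rec <- cache[[key]]
    rec$cached <- TRUE
    return(rec)
  }
  sens <- spc <- dist <- numeric(config$inner_splits)
  for (s in seq_len(config$inner_splits)) {
    sp <- stratified_split(cohort$y, config$inner_split_ratio,
                           derive_seed(config$seed, 7000, s))
    inner_tr <- subset_cohort(cohort, sp$train, require_both_classes = TRUE)
    inner_va <- subset_cohort(cohort, sp$validation)
    res <- tryCatch(suppressWarnings({
      fp <- fit_pipeline(pl, inner_tr, seed = derive_seed(config$seed, 7100, s))
      Xv <- transform_features(fp, inner_va$X)
      spec_cls <- classifier_spec(config$surrogate,
                                  seed = derive_seed(config$seed, 7200),
                                  params = if (config$surrogate == "RF")
                                    list(n_trees = config$surrogate_trees)
                                  else list())
      model <- train_classifier(spec_cls, fp$cohort)
      colnames(Xv) <- NULL
      if (ncol(Xv) != length(model$feature_names)) {
        stop("transform width mismatch")
      }
      scores <- predict_scores(model, Xv)
      pred <- scores >= 0.5
      n1 <- sum(inner_va$y == 1)
      n0 <- sum(inner_va$y == 0)
      sn <- if (n1 > 0) sum(pred & inner_va$y == 1) / n1 else 0
      sp_ <- if (n0 > 0) sum(!pred & inner_va$y == 0) / n0 else 0
      c(sn, sp_, roc_distance(sn, sp_))
    }), error = function(e) {
      warning("pipeline [", format(pl), "] failed in fitness split ", s, ": ",
              conditionMessage(e), "; assigning worst fitness")
      c(0, 0, sqrt(2))
    })
    sens[s] <- res[1]; spc[s] <- res[2]; dist[s] <- res[3]
  }
  rec <- structure(list(pipeline = pl, fitness = mean(dist),
                        per_split = data.frame(sens = sens, spec = spc,
                                               distance = dist),
                        cached = FALSE),
                   class = "fitness_record")
  if (!is.null(cache)) cache[[key]] <- rec
  rec
}

#' Tournament parent selection
#'
#' Two tournaments of `tournament_size` by lower fitness. The second winner
#' is redrawn (bounded) until it differs from the first whenever the
#' population holds at least two distinct pipelines.
#'
#' @param population list of `fitness_record`s (length >= 2).
#' @param seed RNG seed.
#' @param tournament_size tournament size.
#' @return list of two `fitness_record`s.
#' @export
select_parents <- function(population, seed = 1, tournament_size = 3) {
  n <- length(population)
  if (n < 2) stop("population must hold at least 2 records")
  if (n == 2) return(population)  # degenerate: both members are the parents
  set.seed(seed)
  sigs <- vapply(population, function(r) pipeline_signature(r$pipeline),
                 character(1))
  tourney <- function() {
    idx <- sample.int(n, min(tournament_size, n))
    fits <- vapply(population[idx], `[[`, numeric(1), "fitness")
    population[[idx[which.min(fits)]]]
  }
  p1 <- tourney()
  p2 <- tourney()
  if (length(unique(sigs)) >= 2) {
    tries <- 0
    while (identical(pipeline_signature(p2$pipeline),
                     pipeline_signature(p1$pipeline)) && tries < 50) {
      p2 <- tourney()
      tries <- tries + 1
    }
  }
  list(p1, p2)
}

# make any step sequence satisfy the restrictions: drop duplicate methods
# (keep first), drop later members of forbidden pairs, truncate, then drop
# later members of forbidden adjacencies
repair_pipeline <- function(steps, restrictions) {
  out <- list()
  seen <- character(0)
  for (s in steps) {
    if (s$method %in% seen) next
    if (!s$method %in% restrictions$method_pool) next
    conflict <- any(vapply(restrictions$forbidden_pairs, function(pr) {
      s$method %in% pr && any(setdiff(pr, s$method) %in% seen)
    }, logical(1)))
    if (conflict) next
    out[[length(out) + 1]] <- s
    seen <- c(seen, s$method)
  }
  if (length(out) > restrictions$max_length) {
    out <- out[seq_len(restrictions$max_length)]
  }
  repeat {
    methods <- vapply(out, `[[`, character(1), "method")
    bad <- NULL
    if (length(methods) > 1) {
      for (ad in restrictions$forbidden_adjacencies) {
        hit <- which(methods[-length(methods)] == ad[1] &
                     methods[-1] == ad[2])
        if (length(hit) > 0) { bad <- hit[1] + 1; break }
      }
    }
    if (is.null(bad)) break
    out <- out[-bad]
  }
  structure(out, class = "mldp_pipeline")
}

mutate_hyperparams <- function(pl, registry = hyperparam_registry()) {
  steps <- unclass(pl)
  tunable <- which(vapply(steps, function(s) {
    any(vapply(registry[[s$method]], `[[`, logical(1), "tunable"))
  }, logical(1)))
  if (length(tunable) == 0) return(pl)
  i <- if (length(tunable) == 1) tunable else sample(tunable, 1)
  reg <- registry[[steps[[i]]$method]]
  tun_names <- names(reg)[vapply(reg, `[[`, logical(1), "tunable")]
  nm <- if (length(tun_names) == 1) tun_names else sample(tun_names, 1)
  spec <- reg[[nm]]
  v <- if (spec$integer) sample(seq(spec$lower, spec$upper), 1)
       else runif(1, spec$lower, spec$upper)
  hp <- steps[[i]]$hyperparams
  hp[[nm]] <- v
  steps[[i]] <- prep_step(steps[[i]]$method, hp)
  structure(steps, class = "mldp_pipeline")
}

#' Restriction-preserving offspring of two pipelines
#'
#' One-point crossover (a prefix of the first parent followed by a suffix of
#' the second, independent cut points) followed by a repair pass, an optional
#' structural mutation (swap / delete / insert an unused method) and an
#' optional hyperparameter perturbation within registry bounds. The result
#' always satisfies the restrictions; the empty pipeline is allowed.
#'
#' @param p1,p2 valid `mldp_pipeline`s.
#' @param restrictions a [restriction_table()].
#' @param rates named list with `crossover`, `mutation`, `hyper` probabilities.
#' @param seed RNG seed.
#' @param cuts optional fixed cut points `c(c1, c2)` (prefix length of `p1`,
#'   dropped prefix length of `p2`); mainly for testing.
#' @return an `mldp_pipeline`.
#' @export
make_offspring <- function(p1, p2, restrictions = default_restrictions(),
                           rates = list(crossover = 0.9, mutation = 0.3,
                                        hyper = 0.3),
                           seed = 1, cuts = NULL) {
  set.seed(seed)
  s1 <- unclass(p1); s2 <- unclass(p2)
  if (is.null(cuts)) {
    if (runif(1) < rates$crossover && (length(s1) + length(s2)) > 0) {
      c1 <- sample(0:length(s1), 1)
      c2 <- sample(0:length(s2), 1)
    } else {
      c1 <- length(s1); c2 <- length(s2)  # no crossover: child = p1
    }
  } else {
    c1 <- cuts[1]; c2 <- cuts[2]
  }
  child <- c(utils::head(s1, c1), utils::tail(s2, length(s2) - c2))
  child <- repair_pipeline(child, restrictions)
  if (is.null(cuts) && runif(1) < rates$mutation) {
    steps <- unclass(child)
    op <- sample(c("swap", "delete", "insert"), 1)
    if (op == "swap" && length(steps) >= 2) {
      ij <- sample(seq_along(steps), 2)
      steps[ij] <- steps[rev(ij)]
    } else if (op == "delete" && length(steps) >= 1) {
      steps <- steps[-sample(seq_along(steps), 1)]
    } else if (op == "insert") {
      used <- vapply(steps, `[[`, character(1), "method")
      unused <- setdiff(restrictions$method_pool, used)
      if (length(unused) > 0 && length(steps) < restrictions$max_length) {
        m <- if (length(unused) == 1) unused else sample(unused, 1)
        pos <- sample(0:length(steps), 1)
        steps <- append(steps, list(prep_step(m)), after = pos)
      }
    }
    child <- repair_pipeline(steps, restrictions)
  }
  if (is.null(cuts) && runif(1) < rates$hyper && length(child) > 0) {
    child <- mutate_hyperparams(child)
    child <- repair_pipeline(unclass(child), restrictions)
  }
  child
}

# deterministic ranking: fitness, then parsimony, then lexicographic methods
order_population <- function(population) {
  fits <- vapply(population, `[[`, numeric(1), "fitness")
  lens <- vapply(population, function(r) length(r$pipeline), numeric(1))
  sigs <- vapply(population, function(r) pipeline_signature(r$pipeline),
                 character(1))
  population[order(fits, lens, sigs)]
}

#' Run the evolutionary pipeline search
#'
#' Initializes a population of random valid pipelines, then iterates
#' elitism, tournament selection, restriction-preserving offspring and
#' fitness evaluation until the generation budget or a fitness plateau is
#' reached. Fitness only ever consults the training cohort; the returned
#' trace carries an audit log of every sample id touched.
#'
#' @param cohort training [labeled_cohort()].
#' @param restrictions a [restriction_table()].
#' @param config a [search_config()].
#' @param tree optional pre-built [build_pipeline_tree()] (rebuilt otherwise).
#' @return object of class `mldp_search_result`: `best_pipeline`,
#'   `best_fitness`, `trace` (per-generation best/mean), `evaluations`
#'   (non-cached fitness evaluations), `audit_ids`, `population`.
#' @export
run_mldp <- function(cohort, restrictions = default_restrictions(),
                     config = search_config(), tree = NULL) {
  check_training_cohort(cohort)
  tree <- tree %||% build_pipeline_tree(restrictions)
  cache <- new.env(parent = emptyenv())
  audit <- new_audit()
  evals <- 0L
  eval_rec <- function(pl) {
    rec <- evaluate_fitness(pl, cohort, config, cache = cache, audit = audit)
    if (!isTRUE(rec$cached)) evals <<- evals + 1L
    rec
  }
  ld <- NULL
  if (!config$include_empty) {
    avail <- tree$depth_counts[tree$depth_counts > 0]
    avail <- avail[names(avail) != "0"]
    ld <- setNames(rep(1 / length(avail), length(avail)), names(avail))
  }
  population <- lapply(seq_len(config$population_size), function(i) {
    eval_rec(sample_pipeline(tree, length_distribution = ld,
                             seed = derive_seed(config$seed, 100, i)))
  })
  population <- order_population(population)
  best <- population[[1]]
  stall <- 0L
  trace <- data.frame(generation = 0, best_fitness = best$fitness,
                      mean_fitness = mean(vapply(population, `[[`,
                                                 numeric(1), "fitness")))
  for (g in seq_len(config$generations)) {
    nxt <- population[seq_len(config$elitism_count)]
    k <- 0L
    while (length(nxt) < config$population_size) {
      k <- k + 1L
      parents <- select_parents(population,
                                seed = derive_seed(config$seed, 200, g, k),
                                tournament_size = config$tournament_size)
      child <- make_offspring(parents[[1]]$pipeline, parents[[2]]$pipeline,
                              restrictions,
                              rates = list(crossover = config$crossover_rate,
                                           mutation = config$mutation_rate,
                                           hyper = config$hyperparam_mutation_rate),
                              seed = derive_seed(config$seed, 300, g, k))
      if (length(child) == 0 && !config$include_empty) {
        child <- sample_pipeline(tree, length_distribution = ld,
                                 seed = derive_seed(config$seed, 400, g, k))
      }
      nxt[[length(nxt) + 1]] <- eval_rec(child)
    }
    population <- order_population(nxt)
    gen_best <- population[[1]]
    if (gen_best$fitness < best$fitness - 1e-12) {
      best <- gen_best
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    trace <- rbind(trace,
                   data.frame(generation = g, best_fitness = best$fitness,
                              mean_fitness = mean(vapply(population, `[[`,
                                                         numeric(1), "fitness"))))
    if (stall >= config$plateau_patience) break
  }
  structure(list(best_pipeline = best$pipeline, best_fitness = best$fitness,
                 trace = trace, evaluations = evals,
                 audit_ids = audit$ids, population = population,
                 config = config),
            class = "mldp_search_result")
}

#' @export
print.mldp_search_result <- function(x, ...) {
  cat(sprintf("<mldp search> best fitness %.4f after %d evaluations\n",
              x$best_fitness, x$evaluations))
  cat("  best pipeline:", format(x$best_pipeline), "\n")
  invisible(x)
}

#' Random-search baseline over the pipeline tree
#'
#' Evaluates `budget` random pipelines and returns the best; used as the
#' equal-budget comparison arm for the evolutionary search.
#'
#' @inheritParams run_mldp
#' @param budget number of fitness evaluations.
#' @return an `mldp_search_result` (with a flat trace).
#' @export
run_random_search <- function(cohort, restrictions = default_restrictions(),
                              config = search_config(), budget = 50,
                              tree = NULL) {
  check_training_cohort(cohort)
  tree <- tree %||% build_pipeline_tree(restrictions)
  cache <- new.env(parent = emptyenv())
  audit <- new_audit()
  ld <- NULL
  if (!config$include_empty) {
    avail <- tree$depth_counts[tree$depth_counts > 0]
    avail <- avail[names(avail) != "0"]
    ld <- setNames(rep(1 / length(avail), length(avail)), names(avail))
  }
  best <- NULL
  evals <- 0L
  attempts <- 0L
  while (evals < budget && attempts < 100 * budget) {
    attempts <- attempts + 1L
    pl <- sample_pipeline(tree, length_distribution = ld,
                          seed = derive_seed(config$seed, 500, attempts))
    rec <- evaluate_fitness(pl, cohort, config, cache = cache, audit = audit)
    if (!isTRUE(rec$cached)) evals <- evals + 1L
    if (is.null(best) || rec$fitness < best$fitness) best <- rec
  }
  structure(list(best_pipeline = best$pipeline, best_fitness = best$fitness,
                 trace = data.frame(), evaluations = evals,
                 audit_ids = audit$ids, population = list(best),
                 config = config),
            class = "mldp_search_result")
}
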