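## The eight data-preparation operators. Uniform contract: each fit function
## consumes a labeled_cohort and returns list(cohort = <prepared cohort>,
## step = <fitted_step>). Feature-space steps (SFS, PCA) carry transform
## state applicable to unseen data; sample-space steps do not.

new_fitted_step <- function(spec, state = list()) {
  structure(list(spec = spec, scope = method_scope(spec$method), state = state),
            class = "mldp_fitted_step")
}

#' @export
print.mldp_fitted_step <- function(x, ...) {
  cat(sprintf("<fitted %s step %s>\n", x$scope, format(x$spec)))
  invisible(x)
}

# distance-space representation: z-scored on the current training cohort
# so large-magnitude features do not dominate Euclidean neighborhoods
distance_space <- function(X) {
  zs <- zscore_fit(X)
  zscore_apply(X, zs)
}

#' Isolation-forest anomaly scores
#'
#' Ensemble of random partition trees (random feature, random split point
#' between the in-node min and max, depth limit `ceil(log2(psi))`); the
#' anomaly score of a sample is `2^(-E[h(x)] / c(psi))` where `E[h(x)]` is
#' its average path length and `c(psi)` the expected path length of an
#' unsuccessful BST search in a tree of the subsample size.
#'
#' @param X numeric matrix.
#' @param n_trees number of isolation trees.
#' @param subsample_size per-tree subsample size (capped at `nrow(X)`).
#' @param seed RNG seed.
#' @return numeric vector of scores in `(0, 1]`.
#' @export
isolation_scores <- function(X, n_trees = 100, subsample_size = 256, seed = 1) {
  psi <- min(subsample_size, nrow(X))
  depths <- cpp_isolation_depths(as.matrix(X), as.integer(n_trees),
                                 as.integer(psi), as.integer(seed))
  2^(-depths / cpp_iforest_cn(psi))
}

#' Fit and apply isolation-forest outlier removal
#'
#' Removes training samples whose anomaly score exceeds `score_threshold`.
#' Never removes so many samples that a class vanishes: if all members of a
#' class are flagged, none of that class is removed and a warning is raised.
#'
#' @param cohort a [labeled_cohort()] with `n >= 8`.
#' @param n_trees,subsample_size,score_threshold,seed operator hyperparameters.
#' @return `list(cohort = reduced cohort, step = fitted step, scores = scores)`.
#' @export
fit_apply_isolation_forest <- function(cohort, n_trees = 100,
                                       subsample_size = 256,
                                       score_threshold = 0.55, seed = 1) {
  n <- nrow(cohort$X)
  if (n < 8) stop("too few samples for isolation forest (n = ", n, " < 8)")
  scores <- isolation_scores(cohort$X, n_trees, subsample_size, seed)
  flagged <- scores > score_threshold
  for (cls in c(0L, 1L)) {
    in_cls <- cohort$y == cls
    if (any(in_cls) && all(flagged[in_cls])) {
      warning("isolation forest would remove every class-", cls,
              " sample; keeping that class intact")
      flagged[in_cls] <- FALSE
    }
  }
  keep <- which(!flagged)
  spec <- prep_step("IF", list(n_trees = n_trees, subsample_size = subsample_size,
                               score_threshold = score_threshold),
                    check_bounds = FALSE)
  list(cohort = subset_cohort(cohort, keep),
       step = new_fitted_step(spec, list(removed_ids = cohort$sample_ids[flagged])),
       scores = scores)
}

#' R-squared-based sequential forward feature selection
#'
#' Greedy wrapper selection: at each round the feature whose addition
#' maximizes the coefficient of determination of an ordinary-least-squares
#' fit of the binary label on the selected set is added; selection stops at
#' `n_keep` features or when the R-squared improvement falls below `tol`.
#'
#' @param cohort a [labeled_cohort()].
#' @param n_keep maximum number of features to keep (`1 <= n_keep <= p`).
#' @param tol minimum R-squared improvement to continue.
#' @return `list(cohort = feature-subset cohort, step = fitted step)`; the
#'   step state stores the selected indices in selection order and the
#'   per-round R-squared trace.
#' @export
fit_sfs_r2 <- function(cohort, n_keep = 10, tol = 1e-4) {
  X <- cohort$X
  y <- as.numeric(cohort$y)
  p <- ncol(X)
  if (n_keep < 1 || n_keep > p) {
    stop("n_keep must satisfy 1 <= n_keep <= p (got ", n_keep, ", p = ", p, ")")
  }
  sst <- sum((y - mean(y))^2)
  candidate <- which(apply(X, 2, function(v) max(v) > min(v)))
  if (length(candidate) == 0) stop("all feature columns are constant")
  selected <- integer(0)
  r2_trace <- numeric(0)
  r2_prev <- 0
  n <- nrow(X)
  while (length(selected) < n_keep && length(candidate) > 0) {
    best_r2 <- -Inf
    best_j <- NA_integer_
    for (j in candidate) {
      Z <- cbind(1, X[, c(selected, j), drop = FALSE])
      fit <- .lm.fit(Z, y)
      r2 <- 1 - sum(fit$residuals^2) / sst
      if (r2 > best_r2) { best_r2 <- r2; best_j <- j }
    }
    if (length(selected) > 0 && best_r2 - r2_prev < tol) break
    selected <- c(selected, best_j)
    candidate <- setdiff(candidate, best_j)
    r2_prev <- best_r2
    r2_trace <- c(r2_trace, best_r2)
    if (best_r2 >= 1 - 1e-12 || length(selected) >= n - 2) break
  }
  spec <- prep_step("SFS", list(n_keep = n_keep, tol = tol),
                    check_bounds = FALSE)
  step <- new_fitted_step(spec, list(selected = selected,
                                     selected_names = cohort$feature_names[selected],
                                     r2_trace = r2_trace))
  list(cohort = replace_features(cohort, cohort$X[, selected, drop = FALSE],
                                 cohort$feature_names[selected]),
       step = step)
}

#' Principal-component projection
#'
#' Centers the features (no scaling) and projects onto the leading principal
#' components retaining at least `variance_retained` of total variance, or
#' exactly `n_components` if given.
#'
#' @param cohort a [labeled_cohort()] with `n >= 2`.
#' @param variance_retained fraction of variance to retain, in `(0, 1]`.
#' @param n_components exact component count (overrides `variance_retained`).
#' @return `list(cohort = projected cohort, step = fitted step)`; the step
#'   state stores the centering vector and loadings.
#' @export
fit_pca <- function(cohort, variance_retained = 0.95, n_components = NULL) {
  if (nrow(cohort$X) < 2) stop("PCA requires n >= 2")
  if (is.null(n_components) &&
      (variance_retained <= 0 || variance_retained > 1)) {
    stop("variance_retained must lie in (0, 1]")
  }
  pc <- prcomp(cohort$X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  nonzero <- sum(ev > max(ev) * 1e-12)
  if (is.null(n_components)) {
    cum <- cumsum(ev) / sum(ev)
    k <- which(cum >= variance_retained - 1e-12)[1]
    k <- min(k, nonzero)
  } else {
    k <- min(n_components, length(ev))
  }
  k <- max(k, 1L)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  spec <- prep_step("PCA", list(variance_retained =
                                  if (is.null(n_components)) variance_retained
                                  else hyperparam_registry()$PCA$variance_retained$default),
                    check_bounds = FALSE)
  step <- new_fitted_step(spec, list(center = pc$center, rotation = rot,
                                     eigenvalues = ev, n_components = k))
  list(cohort = replace_features(cohort, scores, colnames(scores)), step = step)
}

minority_class <- function(y) if (sum(y == 1) <= sum(y == 0)) 1L else 0L

#' Random minority oversampling
#'
#' Duplicates uniformly sampled minority rows until
#' `minority / majority >= target_ratio`; duplicate rows are flagged in the
#' sample ids by a `_dup` suffix.
#'
#' @param cohort a [labeled_cohort()] with both classes.
#' @param target_ratio desired minority/majority ratio in `(0, 1]`.
#' @param seed RNG seed.
#' @return `list(cohort, step)`.
#' @export
apply_random_oversample <- function(cohort, target_ratio = 1.0, seed = 1) {
  y <- cohort$y
  mc <- minority_class(y)
  n_min <- sum(y == mc); n_maj <- sum(y != mc)
  spec <- prep_step("RO", list(target_ratio = target_ratio),
                    check_bounds = FALSE)
  need <- ceiling(target_ratio * n_maj) - n_min
  if (need <= 0) {
    warning("target_ratio ", target_ratio, " <= current ratio; no-op")
    return(list(cohort = cohort, step = new_fitted_step(spec)))
  }
  set.seed(seed)
  pick <- sample(which(y == mc), need, replace = TRUE)
  Xnew <- rbind(cohort$X, cohort$X[pick, , drop = FALSE])
  ynew <- c(y, y[pick])
  ids <- c(cohort$sample_ids,
           paste0(cohort$sample_ids[pick], "_dup", seq_along(pick)))
  out <- labeled_cohort(Xnew, ynew, sample_ids = ids,
                        feature_names = cohort$feature_names,
                        positive_label_name = cohort$positive_label_name,
                        negative_label_name = cohort$negative_label_name,
                        provenance = cohort$provenance)
  list(cohort = out, step = new_fitted_step(spec))
}

#' Random majority undersampling
#'
#' Removes uniformly sampled majority rows until
#' `minority / majority >= target_ratio`; minority rows are untouched.
#'
#' @inheritParams apply_random_oversample
#' @return `list(cohort, step)`.
#' @export
apply_random_undersample <- function(cohort, target_ratio = 1.0, seed = 1) {
  y <- cohort$y
  mc <- minority_class(y)
  n_min <- sum(y == mc); n_maj <- sum(y != mc)
  spec <- prep_step("RU", list(target_ratio = target_ratio),
                    check_bounds = FALSE)
  keep_maj <- max(min(floor(n_min / target_ratio), n_maj), 1L)
  if (keep_maj >= n_maj) {
    warning("target_ratio ", target_ratio, " <= current ratio; no-op")
    return(list(cohort = cohort, step = new_fitted_step(spec)))
  }
  set.seed(seed)
  maj_keep <- sample(which(y != mc), keep_maj)
  keep <- sort(c(which(y == mc), maj_keep))
  list(cohort = subset_cohort(cohort, keep), step = new_fitted_step(spec))
}

# k nearest minority neighbors (excluding self), in z-scored space;
# returns an n_minority x k index matrix in minority order
minority_neighbors <- function(Xz, min_idx, k) {
  d2 <- euclidean_dist2(Xz[min_idx, , drop = FALSE])
  diag(d2) <- Inf
  res <- matrix(0L, length(min_idx), k)
  for (i in seq_len(nrow(d2))) res[i, ] <- order(d2[i, ])[seq_len(k)]
  res
}

smote_interpolate <- function(cohort, seed_rows, nn_rows, n_new, tag) {
  # seed_rows: candidate minority rows; nn_rows: matrix of their neighbor rows
  # (indices into seed space mapping back to cohort rows via attr)
  pick_seed <- sample(seq_along(seed_rows), n_new, replace = TRUE)
  k <- ncol(nn_rows)
  pick_nn <- sample.int(k, n_new, replace = TRUE)
  u <- runif(n_new)
  Xs <- matrix(0, n_new, ncol(cohort$X))
  for (i in seq_len(n_new)) {
    a <- cohort$X[seed_rows[pick_seed[i]], ]
    b <- cohort$X[attr(nn_rows, "row_map")[nn_rows[pick_seed[i], pick_nn[i]]], ]
    Xs[i, ] <- a + u[i] * (b - a)
  }
  colnames(Xs) <- cohort$feature_names
  Xs
}

#' Synthetic minority oversampling (SMOTE)
#'
#' New minority samples are convex combinations `x + u (x_nn - x)` of a
#' minority sample and one of its `k` Euclidean nearest minority neighbors
#' (neighborhoods computed on z-scored features), generated until
#' `minority / majority >= target_ratio`.
#'
#' @param cohort a [labeled_cohort()]; minority count must be at least 2.
#' @param k_neighbors neighbor count (reduced with a warning when it exceeds
#'   `minority count - 1`).
#' @param target_ratio desired minority/majority ratio in `(0, 1]`.
#' @param seed RNG seed.
#' @return `list(cohort, step)`.
#' @export
apply_smote <- function(cohort, k_neighbors = 5, target_ratio = 1.0, seed = 1) {
  y <- cohort$y
  mc <- minority_class(y)
  min_idx <- which(y == mc)
  n_min <- length(min_idx); n_maj <- sum(y != mc)
  if (n_min < 2) stop("SMOTE requires at least 2 minority samples")
  k <- k_neighbors
  if (k > n_min - 1) {
    warning("k_neighbors reduced from ", k, " to ", n_min - 1)
    k <- n_min - 1
  }
  spec <- prep_step("SMOTE", list(k_neighbors = k_neighbors,
                                  target_ratio = target_ratio),
                    check_bounds = FALSE)
  n_new <- ceiling(target_ratio * n_maj) - n_min
  if (n_new <= 0) {
    warning("target_ratio ", target_ratio, " <= current ratio; no-op")
    return(list(cohort = cohort, step = new_fitted_step(spec)))
  }
  set.seed(seed)
  Xz <- distance_space(cohort$X)
  nn <- minority_neighbors(Xz, min_idx, k)
  attr(nn, "row_map") <- min_idx
  Xs <- smote_interpolate(cohort, min_idx, nn, n_new, "smote")
  out <- labeled_cohort(rbind(cohort$X, Xs), c(y, rep(mc, n_new)),
                        sample_ids = c(cohort$sample_ids,
                                       paste0("synth_smote_", seq_len(n_new))),
                        feature_names = cohort$feature_names,
                        positive_label_name = cohort$positive_label_name,
                        negative_label_name = cohort$negative_label_name,
                        provenance = cohort$provenance)
  list(cohort = out, step = new_fitted_step(spec))
}

# classify minority samples by their m nearest neighbors over ALL samples:
# "safe" (< m/2 majority), "danger" (>= m/2 but < m), "noise" (all m majority)
bsmote_danger_sets <- function(Xz, y, mc, m) {
  min_idx <- which(y == mc)
  d2 <- euclidean_dist2(Xz[min_idx, , drop = FALSE], Xz)
  cls <- character(length(min_idx))
  for (i in seq_along(min_idx)) {
    ord <- order(d2[i, ])
    ord <- ord[ord != min_idx[i]][seq_len(m)]
    n_maj <- sum(y[ord] != mc)
    cls[i] <- if (n_maj == m) "noise" else if (n_maj >= m / 2) "danger" else "safe"
  }
  split(min_idx, factor(cls, levels = c("safe", "danger", "noise")))
}

#' Borderline SMOTE
#'
#' Like [apply_smote()] but synthetic samples are seeded only from the
#' "danger" set: minority samples whose `m` nearest neighbors across all
#' samples contain at least `m/2` (but not all `m`) majority members.
#' Falls back to a warned no-op when the danger set is empty.
#'
#' @inheritParams apply_smote
#' @param m_danger neighborhood size used for the safe/danger/noise triage.
#' @return `list(cohort, step)`.
#' @export
apply_borderline_smote <- function(cohort, k_neighbors = 5, m_danger = 10,
                                   target_ratio = 1.0, seed = 1) {
  y <- cohort$y
  mc <- minority_class(y)
  min_idx <- which(y == mc)
  n_min <- length(min_idx); n_maj <- sum(y != mc)
  if (n_min < 2) stop("BSMOTE requires at least 2 minority samples")
  k <- min(k_neighbors, n_min - 1)
  if (k < k_neighbors) warning("k_neighbors reduced from ", k_neighbors, " to ", k)
  m <- min(m_danger, nrow(cohort$X) - 1)
  spec <- prep_step("BSMOTE", list(k_neighbors = k_neighbors,
                                   m_danger = m_danger,
                                   target_ratio = target_ratio),
                    check_bounds = FALSE)
  n_new <- ceiling(target_ratio * n_maj) - n_min
  if (n_new <= 0) {
    warning("target_ratio ", target_ratio, " <= current ratio; no-op")
    return(list(cohort = cohort, step = new_fitted_step(spec)))
  }
  set.seed(seed)
  Xz <- distance_space(cohort$X)
  sets <- bsmote_danger_sets(Xz, y, mc, m)
  danger <- sets$danger
  if (length(danger) == 0) {
    warning("BSMOTE: empty danger set; no-op")
    return(list(cohort = cohort,
                step = new_fitted_step(spec, list(danger = integer(0)))))
  }
  nn <- minority_neighbors(Xz, min_idx, k)
  attr(nn, "row_map") <- min_idx
  # restrict the seed pool to danger members (rows of nn indexed in minority order)
  danger_pos <- match(danger, min_idx)
  pick_seed <- sample(danger_pos, n_new, replace = TRUE)
  pick_nn <- sample.int(k, n_new, replace = TRUE)
  u <- runif(n_new)
  Xs <- matrix(0, n_new, ncol(cohort$X))
  for (i in seq_len(n_new)) {
    a <- cohort$X[min_idx[pick_seed[i]], ]
    b <- cohort$X[min_idx[nn[pick_seed[i], pick_nn[i]]], ]
    Xs[i, ] <- a + u[i] * (b - a)
  }
  colnames(Xs) <- cohort$feature_names
  out <- labeled_cohort(rbind(cohort$X, Xs), c(y, rep(mc, n_new)),
                        sample_ids = c(cohort$sample_ids,
                                       paste0("synth_bsmote_", seq_len(n_new))),
                        feature_names = cohort$feature_names,
                        positive_label_name = cohort$positive_label_name,
                        negative_label_name = cohort$negative_label_name,
                        provenance = cohort$provenance)
  list(cohort = out, step = new_fitted_step(spec, list(danger = danger)))
}

#' Tomek-link pairs of a cohort
#'
#' A Tomek link is an opposite-class pair that are mutual Euclidean nearest
#' neighbors (computed on z-scored features). Deterministic.
#'
#' @param cohort a [labeled_cohort()].
#' @return two-column integer matrix of row indices `(i, j)`, `i < j`.
#' @export
tomek_links <- function(cohort) {
  Xz <- distance_space(cohort$X)
  d2 <- euclidean_dist2(Xz)
  diag(d2) <- Inf
  nn <- apply(d2, 1, which.min)
  y <- cohort$y
  links <- list()
  for (i in seq_along(nn)) {
    j <- nn[i]
    if (j > i && nn[j] == i && y[i] != y[j]) links[[length(links) + 1]] <- c(i, j)
  }
  if (length(links) == 0) return(matrix(integer(0), 0, 2))
  do.call(rbind, links)
}

#' Tomek-link data purification
#'
#' Removes the majority-class member of every Tomek link (removing minority
#' members would aggravate the imbalance that other steps correct).
#' Deterministic; guards against emptying a class.
#'
#' @param cohort a [labeled_cohort()] with both classes.
#' @return `list(cohort, step)`.
#' @export
apply_tomek_links <- function(cohort) {
  y <- cohort$y
  if (length(unique(y)) < 2) stop("Tomek links require both classes")
  mc <- minority_class(y)
  links <- tomek_links(cohort)
  spec <- prep_step("TL")
  if (nrow(links) == 0) {
    return(list(cohort = cohort, step = new_fitted_step(spec, list(links = links))))
  }
  drop <- unique(as.vector(links)[y[as.vector(links)] != mc])
  if (length(drop) >= sum(y != mc)) {
    warning("Tomek-link removal would empty the majority class; keeping one sample")
    drop <- drop[-1]
  }
  keep <- setdiff(seq_along(y), drop)
  list(cohort = subset_cohort(cohort, keep),
       step = new_fitted_step(spec, list(links = links,
                                         removed_ids = cohort$sample_ids[drop])))
}

## ---- pipeline fitting ------------------------------------------------------

fit_one_step <- function(step, cohort, seed) {
  hp <- step$hyperparams
  switch(step$method,
    IF = fit_apply_isolation_forest(cohort, n_trees = hp$n_trees,
                                    subsample_size = hp$subsample_size,
                                    score_threshold = hp$score_threshold,
                                    seed = seed)[c("cohort", "step")],
    SFS = fit_sfs_r2(cohort, n_keep = min(hp$n_keep, ncol(cohort$X)),
                     tol = hp$tol),
    PCA = fit_pca(cohort, variance_retained = hp$variance_retained),
    RO = apply_random_oversample(cohort, target_ratio = hp$target_ratio,
                                 seed = seed),
    RU = apply_random_undersample(cohort, target_ratio = hp$target_ratio,
                                  seed = seed),
    SMOTE = apply_smote(cohort, k_neighbors = hp$k_neighbors,
                        target_ratio = hp$target_ratio, seed = seed),
    BSMOTE = apply_borderline_smote(cohort, k_neighbors = hp$k_neighbors,
                                    m_danger = hp$m_danger,
                                    target_ratio = hp$target_ratio, seed = seed),
    TL = apply_tomek_links(cohort),
    stop("unknown method_id '", step$method, "'"))
}

#' Fit a pipeline on training data
#'
#' Applies every step in order on the training cohort, recording the fitted
#' feature-space transforms. Resampling/removal steps act on the training
#' samples only and leave no state applicable to unseen data.
#'
#' @param pl an `mldp_pipeline`.
#' @param cohort training [labeled_cohort()].
#' @param seed base seed; per-step seeds are derived deterministically.
#' @return object of class `mldp_fitted_pipeline`: list with the prepared
#'   `cohort`, the list of fitted `steps`, the originating `pipeline` and the
#'   training `input_ids`.
#' @export
fit_pipeline <- function(pl, cohort, seed = 1) {
  stopifnot(inherits(pl, "mldp_pipeline"))
  current <- cohort
  fitted <- vector("list", length(pl))
  for (i in seq_along(pl)) {
    res <- fit_one_step(unclass(pl)[[i]], current, derive_seed(seed, i))
    current <- res$cohort
    fitted[[i]] <- res$step
    if (length(unique(current$y)) < 2) {
      stop("pipeline step ", format(unclass(pl)[[i]]),
           " removed every sample of one class")
    }
  }
  structure(list(cohort = current, steps = fitted, pipeline = pl,
                 input_ids = cohort$sample_ids, seed = seed),
            class = "mldp_fitted_pipeline")
}

#' Apply a single fitted feature-space step to a feature matrix
#'
#' @param step a fitted step from [fit_pipeline()] with scope
#'   `feature_space` (SFS or PCA); applying a sample-space step to unseen
#'   data is an error.
#' @param X numeric matrix.
#' @return transformed matrix.
#' @export
apply_fitted_step <- function(step, X) {
  if (step$scope != "feature_space") {
    stop("step ", step$spec$method,
         " operates in sample space and cannot be applied to unseen data")
  }
  switch(step$spec$method,
    SFS = X[, step$state$selected, drop = FALSE],
    PCA = {
      Xc <- sweep(as.matrix(X), 2, step$state$center, "-")
      Xc %*% step$state$rotation
    })
}

#' Apply the feature-space part of a fitted pipeline to validation data
#'
#' Only SFS/PCA transforms are replayed, in pipeline order; sample counts are
#' never altered.
#'
#' @param fp an `mldp_fitted_pipeline`.
#' @param X validation feature matrix (original feature space).
#' @return transformed matrix with `nrow(X)` rows.
#' @export
transform_features <- function(fp, X) {
  X <- as.matrix(X)
  for (step in fp$steps) {
    if (step$scope == "feature_space") X <- apply_fitted_step(step, X)
  }
  X
}
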