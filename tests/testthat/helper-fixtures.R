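# Shared fixtures and independent brute-force oracles. Oracles deliberately
# reimplement the quantities from their definitions (no calls into the
# package paths they check).

make_cohort <- function(X, y, ...) {
  labeled_cohort(as.matrix(X), y, ...)
}

# small random two-class cohort with Gaussian features
random_cohort <- function(n = 24, p = 3, seed = 1, minority_fraction = 0.4) {
  set.seed(seed)
  n1 <- max(2, round(n * minority_fraction))
  y <- sample(c(rep(1L, n1), rep(0L, n - n1)))
  X <- matrix(rnorm(n * p), n, p) + 0.5 * y
  make_cohort(X, y)
}

# brute-force z-scoring identical by definition to the operator convention
oracle_zscore <- function(X) {
  for (j in seq_len(ncol(X))) {
    s <- sd(X[, j])
    if (!is.finite(s) || s < 1e-12) s <- 1
    X[, j] <- (X[, j] - mean(X[, j])) / s
  }
  X
}

# O(n^2) Tomek-link enumeration straight from the definition: opposite-class
# mutual Euclidean nearest neighbours on z-scored features
oracle_tomek <- function(cohort) {
  X <- oracle_zscore(cohort$X)
  n <- nrow(X)
  D <- as.matrix(dist(X))
  diag(D) <- Inf
  links <- matrix(integer(0), 0, 2)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (cohort$y[i] == cohort$y[j]) next
      if (which.min(D[i, ]) == j && which.min(D[j, ]) == i) {
        links <- rbind(links, c(i, j))
      }
    }
  }
  links
}

oracle_borderline <- function(cohort) {
  links <- oracle_tomek(cohort)
  if (nrow(links) == 0) return(0)
  minc <- if (sum(cohort$y == 1) <= sum(cohort$y == 0)) 1L else 0L
  members <- unique(as.vector(links))
  100 * sum(cohort$y[members] == minc) / nrow(cohort$X)
}

# pairwise-comparison AUC (ties count 1/2)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# exhaustive enumeration of all ordered sequences of distinct pool members up
# to max_len, filtered by the restriction clauses, straight from definitions
oracle_enumerate <- function(pool, max_len, forbidden_pairs = list(),
                             forbidden_adj = list()) {
  out <- list(character(0))
  grow <- function(seq_so_far) {
    if (length(seq_so_far) >= max_len) return(invisible())
    for (m in setdiff(pool, seq_so_far)) {
      cand <- c(seq_so_far, m)
      ok <- TRUE
      for (pr in forbidden_pairs) if (all(pr %in% cand)) ok <- FALSE
      if (ok && length(cand) > 1) {
        for (ad in forbidden_adj) {
          k <- length(cand)
          if (cand[k - 1] == ad[1] && cand[k] == ad[2]) ok <- FALSE
        }
      }
      if (ok) {
        out[[length(out) + 1]] <<- cand
        grow(cand)
      }
    }
  }
  grow(character(0))
  out
}

canon_pipeline_set <- function(lst) {
  sort(vapply(lst, function(v) paste(v, collapse = ">"), character(1)))
}

# single-feature OLS R^2, by definition
oracle_r2 <- function(x, y) {
  f <- lm(y ~ x)
  1 - sum(residuals(f)^2) / sum((y - mean(y))^2)
}

expect_no_leak <- function(audit_ids, validation_ids) {
  expect_length(intersect(audit_ids, validation_ids), 0)
}

# small fast search budget used across tests (budget knob, not a tuned value)
test_search_config <- function(seed = 1, ...) {
  search_config(population_size = 8, generations = 4, plateau_patience = 3,
                inner_splits = 3, surrogate_trees = 40, seed = seed, ...)
}

stratified_split_for_test <- function(y, frac, seed) {
  mldprep:::stratified_split(y, frac, seed)
}
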