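`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child RNG seed from a base seed and stream offsets
#'
#' Counter-based derivation: adding folds/generations never reshuffles the
#' seeds of earlier folds. Result is always in `[1, 2^31 - 2]` so it is a
#' valid R integer seed.
#'
#' @param base integer base seed.
#' @param ... integer offsets identifying the stream (fold index, step index,
#'   ...); combined left to right.
#' @return a single integer seed.
#' @export
derive_seed <- function(base, ...) {
  offs <- c(...)
  s <- as.double(base) %% 2147483647
  for (k in offs) {
    # affine step mod a Mersenne prime; doubles are exact here (< 2^53)
    s <- (s * 48271 + as.double(k) + 1) %% 2147483647
  }
  as.integer(s + 1)
}

# z-scoring helper shared by distance-based operators and scale-sensitive
# classifiers; zero-variance columns are left unscaled (divisor 1)
zscore_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  list(center = ctr, scale = scl)
}

zscore_apply <- function(X, zs) {
  sweep(sweep(X, 2, zs$center, "-"), 2, zs$scale, "/")
}

# stratified split of a 0/1 label vector into train/validation index sets
stratified_split <- function(y, train_fraction, seed) {
  set.seed(seed)
  idx0 <- which(y == 0)
  idx1 <- which(y == 1)
  n0 <- max(1L, round(length(idx0) * train_fraction))
  n1 <- max(1L, round(length(idx1) * train_fraction))
  n0 <- min(n0, length(idx0) - 1L)
  n1 <- min(n1, length(idx1) - 1L)
  if (n0 < 1L || n1 < 1L) {
    stop("cohort too small for a stratified split with both classes on each side")
  }
  tr <- c(sample(idx0, n0), sample(idx1, n1))
  tr <- sort(tr)
  list(train = tr, validation = setdiff(seq_along(y), tr))
}

euclidean_dist2 <- function(A, B = NULL) {
  # squared Euclidean cross-distance matrix
  if (is.null(B)) B <- A
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}
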