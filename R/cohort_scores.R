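#' Outlier score of a cohort
#'
#' Percentage of samples flagged by the isolation forest (anomaly score above
#' the threshold), without removing any sample.
#'
#' @param cohort a [labeled_cohort()] with `n >= 8`.
#' @param n_trees,subsample_size,score_threshold,seed isolation-forest
#'   parameters (defaults match the IF preparation operator).
#' @return percentage in `[0, 100]`.
#' @export
outlier_score <- function(cohort, n_trees = 100, subsample_size = 256,
                          score_threshold = 0.55, seed = 1) {
  if (nrow(cohort$X) < 8) stop("too few samples (n < 8)")
  scores <- isolation_scores(cohort$X, n_trees, subsample_size, seed)
  100 * mean(scores > score_threshold)
}

#' Borderline score of a cohort
#'
#' Percentage of samples that are minority-class members of at least one
#' Tomek link, relative to the total sample count. Deterministic.
#'
#' @param cohort a [labeled_cohort()] with both classes.
#' @return percentage in `[0, 100]`.
#' @export
borderline_score <- function(cohort) {
  if (length(unique(cohort$y)) < 2) stop("borderline score requires both classes")
  links <- tomek_links(cohort)
  if (nrow(links) == 0) return(0)
  mc <- minority_class(cohort$y)
  members <- unique(as.vector(links))
  100 * sum(cohort$y[members] == mc) / nrow(cohort$X)
}

#' Cohort characteristic scores
#'
#' Outlier and borderline diagnostics, either on the whole cohort
#' (`mode = "whole"`) or averaged over the training subsets of a Monte-Carlo
#' split plan (`mode = "folds"`), matching the fold-averaged reporting
#' convention of cross-validated studies.
#'
#' @param cohort a [labeled_cohort()].
#' @param mode `"whole"` or `"folds"`.
#' @param plan a [split_plan()] used when `mode = "folds"`.
#' @param n_trees,subsample_size,score_threshold,seed isolation-forest
#'   parameters; in fold mode per-fold seeds derive from `seed`.
#' @return list with `outlier_score` and `borderline_score` (percentages);
#'   fold mode adds a `per_fold` data.frame.
#' @export
cohort_scores <- function(cohort, mode = c("whole", "folds"),
                          plan = split_plan(folds = 20), n_trees = 100,
                          subsample_size = 256, score_threshold = 0.55,
                          seed = 1) {
  mode <- match.arg(mode)
  if (mode == "whole") {
    return(list(outlier_score = outlier_score(cohort, n_trees, subsample_size,
                                              score_threshold, seed),
                borderline_score = borderline_score(cohort)))
  }
  splits <- make_splits(cohort, plan)
  os <- bs <- numeric(length(splits))
  for (i in seq_along(splits)) {
    tr <- subset_cohort(cohort, splits[[i]]$train)
    os[i] <- outlier_score(tr, n_trees, subsample_size, score_threshold,
                           seed = derive_seed(seed, i, 101))
    bs[i] <- borderline_score(tr)
  }
  list(outlier_score = mean(os), borderline_score = mean(bs),
       per_fold = data.frame(fold = seq_along(splits),
                             outlier_score = os, borderline_score = bs))
}
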