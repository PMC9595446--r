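#' Cross-validation split plan
#'
#' Monte-Carlo mode draws `folds` independent stratified random
#' training/validation splits; dual-center mode uses one cohort for training
#' and a second, independent cohort for validation (a single fold).
#'
#' @param mode `"monte_carlo"` or `"dual_center"`.
#' @param folds number of random splits (forced to 1 in dual-center mode).
#' @param train_fraction training fraction per split.
#' @param stratified preserve class proportions per split (within one
#'   sample); prevents single-class validation sets at small n.
#' @param seed base seed; per-fold seeds derive deterministically.
#' @return object of class `split_plan`.
#' @export
split_plan <- function(mode = c("monte_carlo", "dual_center"), folds = 100,
                       train_fraction = 0.8, stratified = TRUE, seed = 1) {
  mode <- match.arg(mode)
  if (mode == "dual_center") folds <- 1
  structure(list(mode = mode, folds = folds, train_fraction = train_fraction,
                 stratified = stratified, seed = as.integer(seed)),
            class = "split_plan")
}

#' Generate train/validation index pairs
#'
#' @param cohort a [labeled_cohort()] (or bare 0/1 label vector).
#' @param plan a [split_plan()] in Monte-Carlo mode; `n >= 10` required.
#' @return list of `list(train, validation)` integer index vectors; disjoint
#'   and exhaustive per fold.
#' @export
make_splits <- function(cohort, plan = split_plan()) {
  y <- if (inherits(cohort, "labeled_cohort")) cohort$y else as.integer(cohort)
  if (plan$mode != "monte_carlo") {
    stop("make_splits applies to monte_carlo plans; dual_center uses two cohorts")
  }
  if (length(y) < 10) stop("Monte-Carlo mode requires n >= 10")
  lapply(seq_len(plan$folds), function(i) {
    fseed <- derive_seed(plan$seed, i)
    if (plan$stratified) {
      stratified_split(y, plan$train_fraction, fseed)
    } else {
      for (try in 1:100) {
        set.seed(derive_seed(fseed, try))
        n_tr <- round(length(y) * plan$train_fraction)
        tr <- sort(sample(seq_along(y), n_tr))
        va <- setdiff(seq_along(y), tr)
        if (length(unique(y[tr])) == 2 && length(va) > 0) {
          return(list(train = tr, validation = va))
        }
      }
      stop("could not draw a split with both classes in training")
    }
  })
}

#' Confusion-matrix analytics
#'
#' @param TP,FP,TN,FN non-negative counts.
#' @return named numeric vector with `ACC`, `SNS`, `SPC`, `PPV`, `NPV`;
#'   a metric with a zero denominator is `NA` (undefined-flagged), never
#'   silently 0.
#' @export
confusion_metrics <- function(TP, FP, TN, FN) {
  if (any(c(TP, FP, TN, FN) < 0)) stop("counts must be non-negative")
  n <- TP + FP + TN + FN
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  c(ACC = safe(TP + TN, n),
    SNS = safe(TP, TP + FN),
    SPC = safe(TN, TN + FP),
    PPV = safe(TP, TP + FP),
    NPV = safe(TN, TN + FN))
}

#' Rank-based AUC (Mann-Whitney, midrank ties)
#'
#' @param scores numeric score vector.
#' @param labels 0/1 labels, both classes present.
#' @return the area under the ROC curve.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC requires both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-way ANOVA p-value across two groups of fold-wise metrics
#'
#' @param group_a,group_b numeric vectors (each `n >= 2`).
#' @return p-value; when the pooled within-group variance is zero the
#'   convention `p = 1` is returned with attribute `flag = "zero-variance"`.
#' @export
anova_p <- function(group_a, group_b) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 finite values")
  }
  na <- length(group_a); nb <- length(group_b)
  gm <- mean(c(group_a, group_b))
  ssb <- na * (mean(group_a) - gm)^2 + nb * (mean(group_b) - gm)^2
  ssw <- sum((group_a - mean(group_a))^2) + sum((group_b - mean(group_b))^2)
  dfb <- 1
  dfw <- na + nb - 2
  if (ssw < 1e-300) {
    out <- 1
    attr(out, "flag") <- "zero-variance"
    return(out)
  }
  f <- (ssb / dfb) / (ssw / dfw)
  pf(f, dfb, dfw, lower.tail = FALSE)
}

#' t-based 95% confidence interval of the mean
#'
#' @param values numeric vector, `n >= 2`.
#' @return `c(low, high)`: mean +/- t(0.975, n-1) * sd / sqrt(n).
#' @export
ci95 <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop("ci95 requires at least 2 values")
  m <- mean(values)
  half <- qt(0.975, n - 1) * sd(values) / sqrt(n)
  c(low = m - half, high = m + half)
}

#' The fixed manual data-preparation baseline
#'
#' Feature selection followed by SMOTE at registry defaults — the
#' literature-style manually chosen pipeline used as a comparison arm.
#'
#' @return an `mldp_pipeline` with steps `SFS`, `SMOTE`.
#' @export
manual_pipeline <- function() pipeline("SFS", "SMOTE")

fold_metrics <- function(scores, y_true) {
  pred <- as.integer(scores >= 0.5)
  cm <- confusion_metrics(TP = sum(pred == 1 & y_true == 1),
                          FP = sum(pred == 1 & y_true == 0),
                          TN = sum(pred == 0 & y_true == 0),
                          FN = sum(pred == 0 & y_true == 1))
  auc <- if (length(unique(y_true)) == 2) auc_rank(scores, y_true) else NA_real_
  c(cm, AUC = auc)
}

#' Run the full comparison experiment
#'
#' Per fold and per comparison arm — `"none"` (as-is data), `"mldp"`
#' (evolutionary pipeline search on the training split) and `"manual"`
#' ([manual_pipeline()]) — the training split is prepared, only the
#' feature-space transforms are replayed on the validation split, every
#' classifier scheme is trained and scored, and confusion-matrix analytics
#' are collected. Aggregates mean/SD/CI95 per (arm, scheme, metric), ANOVA
#' p-values (MLDP vs no preparation) and the preparation-method occurrence
#' table across folds. A leakage guard asserts that no validation sample id
#' was ever touched during pipeline selection or preparation.
#'
#' @param cohort training [labeled_cohort()].
#' @param plan a [split_plan()].
#' @param restrictions a [restriction_table()].
#' @param config a [search_config()] for the MLDP arm.
#' @param schemes classifier scheme ids.
#' @param arms subset of `c("none", "mldp", "manual")`.
#' @param validation_cohort second-center cohort (dual-center mode only);
#'   features are aligned by name to the training cohort.
#' @return object of class `mldp_cv_report`: `metrics` (long per-fold
#'   data.frame), `summary` (mean/sd/CI95), `summary_pooled` (metrics over
#'   pooled validation predictions), `anova` (p per scheme/metric),
#'   `occurrence` (percent of folds whose selected pipeline contains each
#'   method), `pipelines` (per-fold selected pipeline strings), `plan`.
#' @export
run_experiment <- function(cohort, plan = split_plan(),
                           restrictions = default_restrictions(),
                           config = search_config(),
                           schemes = c("RF", "MG", "SVM", "XGB", "NN"),
                           arms = c("none", "mldp", "manual"),
                           validation_cohort = NULL) {
  arms <- match.arg(arms, several.ok = TRUE)
  if (plan$mode == "dual_center") {
    if (is.null(validation_cohort)) {
      stop("dual_center mode requires a validation_cohort")
    }
    miss <- setdiff(cohort$feature_names, validation_cohort$feature_names)
    if (length(miss) > 0) {
      stop("validation cohort lacks feature(s): ", paste(utils::head(miss, 3),
                                                         collapse = ","))
    }
    validation_cohort <- replace_features(
      validation_cohort,
      validation_cohort$X[, cohort$feature_names, drop = FALSE],
      cohort$feature_names)
    splits <- list(list(train = NULL, validation = NULL))
  } else {
    splits <- make_splits(cohort, plan)
  }
  tree <- build_pipeline_tree(restrictions)
  rows <- list()
  pooled <- list()
  pipelines <- character(length(splits))
  occ_methods <- restrictions$method_pool
  occur <- matrix(0, nrow = length(splits), ncol = length(occ_methods),
                  dimnames = list(NULL, occ_methods))

  for (f in seq_along(splits)) {
    if (plan$mode == "dual_center") {
      train_c <- cohort
      val_c <- validation_cohort
    } else {
      train_c <- subset_cohort(cohort, splits[[f]]$train,
                               require_both_classes = TRUE)
      val_c <- subset_cohort(cohort, splits[[f]]$validation)
    }
    val_ids <- val_c$sample_ids
    fseed <- derive_seed(plan$seed, 900, f)
    for (arm in arms) {
      if (arm == "none") {
        prep_train <- train_c
        val_X <- val_c$X
      } else {
        if (arm == "mldp") {
          cfg <- config
          cfg$seed <- derive_seed(fseed, 1)
          sres <- run_mldp(train_c, restrictions, cfg, tree = tree)
          pl <- sres$best_pipeline
          if (plan$mode == "monte_carlo" &&
              any(sres$audit_ids %in% val_ids)) {
            stop("leakage guard: validation sample id touched during search")
          }
          pipelines[f] <- format(pl)
          occur[f, pipeline_methods(pl)] <- 1
        } else {
          pl <- manual_pipeline()
        }
        fp <- tryCatch(
          suppressWarnings(fit_pipeline(pl, train_c,
                                        seed = derive_seed(fseed, 2))),
          error = function(e) NULL)
        if (is.null(fp)) {
          # degenerate pipeline on this fold: fall back to unprepared data
          prep_train <- train_c
          val_X <- val_c$X
        } else {
          if (plan$mode == "monte_carlo" && any(fp$input_ids %in% val_ids)) {
            stop("leakage guard: validation sample id in a sample-space operator input")
          }
          prep_train <- fp$cohort
          val_X <- transform_features(fp, val_c$X)
        }
      }
      if (nrow(val_X) != nrow(val_c$X)) {
        stop("feature-space contract violated: validation row count changed")
      }
      for (scheme in schemes) {
        model <- train_classifier(
          classifier_spec(scheme, seed = derive_seed(fseed, 3)), prep_train)
        Xv <- val_X
        colnames(Xv) <- model$feature_names
        scores <- predict_scores(model, Xv)
        m <- fold_metrics(scores, val_c$y)
        rows[[length(rows) + 1]] <- data.frame(
          fold = f, arm = arm, scheme = scheme, t(m))
        pooled[[length(pooled) + 1]] <- data.frame(
          arm = arm, scheme = scheme, score = scores, y = val_c$y)
      }
    }
  }
  metrics <- do.call(rbind, rows)
  pooled <- do.call(rbind, pooled)
  metric_names <- c("ACC", "SNS", "SPC", "PPV", "NPV", "AUC")

  summ <- do.call(rbind, lapply(split(metrics, metrics[c("arm", "scheme")],
                                      drop = TRUE), function(d) {
    do.call(rbind, lapply(metric_names, function(mn) {
      v <- d[[mn]][is.finite(d[[mn]])]
      ci <- if (length(v) >= 2) ci95(v) else c(low = NA_real_, high = NA_real_)
      data.frame(arm = d$arm[1], scheme = d$scheme[1], metric = mn,
                 mean = mean(v), sd = if (length(v) >= 2) sd(v) else NA_real_,
                 ci_low = ci[["low"]], ci_high = ci[["high"]],
                 n_folds = length(v))
    }))
  }))
  rownames(summ) <- NULL

  summ_pooled <- do.call(rbind, lapply(split(pooled, pooled[c("arm", "scheme")],
                                             drop = TRUE), function(d) {
    m <- fold_metrics(d$score, d$y)
    data.frame(arm = d$arm[1], scheme = d$scheme[1], t(m))
  }))
  rownames(summ_pooled) <- NULL

  anova_tab <- NULL
  if (all(c("none", "mldp") %in% arms) && length(splits) >= 2) {
    anova_tab <- do.call(rbind, lapply(schemes, function(sc) {
      do.call(rbind, lapply(metric_names, function(mn) {
        a <- metrics[[mn]][metrics$arm == "mldp" & metrics$scheme == sc]
        b <- metrics[[mn]][metrics$arm == "none" & metrics$scheme == sc]
        p <- tryCatch(as.numeric(anova_p(a, b)), error = function(e) NA_real_)
        data.frame(scheme = sc, metric = mn, p_value = p)
      }))
    }))
  }

  occurrence <- if ("mldp" %in% arms) 100 * colMeans(occur) else NULL

  structure(list(metrics = metrics, summary = summ,
                 summary_pooled = summ_pooled, anova = anova_tab,
                 occurrence = occurrence,
                 pipelines = pipelines, plan = plan, arms = arms,
                 schemes = schemes),
            class = "mldp_cv_report")
}

#' @export
print.mldp_cv_report <- function(x, digits = 2, ...) {
  cat(sprintf("<mldp_cv_report> %s, %d fold(s), arms: %s\n",
              x$plan$mode, x$plan$folds, paste(x$arms, collapse = ", ")))
  auc <- x$summary[x$summary$metric == "AUC", ]
  if (nrow(auc) > 0) {
    wide <- reshape(auc[c("arm", "scheme", "mean")], direction = "wide",
                    idvar = "scheme", timevar = "arm")
    names(wide) <- sub("^mean\\.", "AUC.", names(wide))
    print(format(wide, digits = digits), row.names = FALSE)
  }
  if (!is.null(x$occurrence)) {
    cat("method occurrence [%]:\n")
    print(round(x$occurrence, 1))
  }
  invisible(x)
}
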