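## Five prediction-model schemes behind one train/score interface, all at
## registered fixed defaults (no per-experiment tuning). Scale-sensitive
## schemes (SVM, NN, MG) z-score features internally, fitted on training
## data; the tree ensembles consume raw features.

classifier_defaults <- function() {
  list(
    RF  = list(n_trees = 100, min_node = 1, max_depth = 30, mtry = NA),
    MG  = list(epsilon = 1e-6, shrinkage = 0.1),
    SVM = list(C = 1, gamma = "scale"),
    XGB = list(n_rounds = 100, max_depth = 6, eta = 0.3, lambda = 1,
               min_node = 1),
    NN  = list(hidden = 32, epochs = 200, learning_rate = 0.01))
}

#' Specify a classifier scheme
#'
#' @param scheme one of `"RF"`, `"MG"`, `"SVM"`, `"XGB"`, `"NN"`.
#' @param seed RNG seed (bootstraps, weight initialization).
#' @param params named overrides of the registered defaults; intended for
#'   budget control (e.g. fewer surrogate trees), not tuning.
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(scheme = c("RF", "MG", "SVM", "XGB", "NN"),
                            seed = 1, params = list()) {
  scheme <- match.arg(scheme)
  defaults <- classifier_defaults()[[scheme]]
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown parameter(s) for ", scheme, ": ", paste(unknown, collapse = ","))
  }
  defaults[names(params)] <- params
  structure(list(scheme = scheme, seed = as.integer(seed), params = defaults),
            class = "classifier_spec")
}

check_training_cohort <- function(cohort) {
  if (length(unique(cohort$y)) < 2) stop("training cohort has a single class")
  if (any(!is.finite(cohort$X))) stop("training features contain NaN/Inf")
}

#' Train a classifier scheme on a prepared cohort
#'
#' @param spec a [classifier_spec()].
#' @param cohort a [labeled_cohort()] with both classes.
#' @return object of class `mldp_model` carrying the fitted state and the
#'   feature names seen at fit time.
#' @export
train_classifier <- function(spec, cohort) {
  stopifnot(inherits(spec, "classifier_spec"))
  check_training_cohort(cohort)
  X <- cohort$X
  y <- cohort$y
  p <- spec$params
  fit <- switch(spec$scheme,
    RF = {
      mtry <- if (is.na(p$mtry)) max(1L, floor(sqrt(ncol(X)))) else p$mtry
      cpp_grow_forest(X, as.numeric(y), as.integer(p$n_trees),
                      as.integer(mtry), as.integer(p$min_node),
                      as.integer(p$max_depth), spec$seed)
    },
    MG = mg_fit(X, y, epsilon = p$epsilon, shrinkage = p$shrinkage),
    SVM = svm_fit(X, y, C = p$C, gamma = p$gamma),
    XGB = xgb_fit(X, y, n_rounds = p$n_rounds, max_depth = p$max_depth,
                  eta = p$eta, lambda = p$lambda, min_node = p$min_node),
    NN = nn_fit(X, y, hidden = p$hidden, epochs = p$epochs,
                lr = p$learning_rate, seed = spec$seed))
  structure(list(scheme = spec$scheme, spec = spec, fit = fit,
                 feature_names = cohort$feature_names),
            class = "mldp_model")
}

#' Predict positive-class scores
#'
#' @param model an `mldp_model` from [train_classifier()].
#' @param X numeric matrix with exactly the feature columns (names and order)
#'   seen at fit time; a `labeled_cohort` is also accepted.
#' @return numeric score vector in `[0, 1]`; threshold 0.5 yields class labels.
#' @export
predict_scores <- function(model, X) {
  if (inherits(X, "labeled_cohort")) X <- X$X
  X <- as.matrix(X)
  if (ncol(X) != length(model$feature_names) ||
      (!is.null(colnames(X)) && !identical(colnames(X), model$feature_names))) {
    stop("feature mismatch: model was fitted on ",
         length(model$feature_names), " feature(s) [",
         paste(utils::head(model$feature_names, 3), collapse = ","),
         ", ...]; got ", ncol(X))
  }
  s <- switch(model$scheme,
    RF = cpp_predict_forest(model$fit, X),
    MG = mg_score(model$fit, X),
    SVM = svm_score(model$fit, X),
    XGB = xgb_score(model$fit, X),
    NN = nn_score(model$fit, X))
  pmin(pmax(as.numeric(s), 0), 1)
}

#' @export
print.mldp_model <- function(x, ...) {
  cat(sprintf("<mldp_model %s, %d features>\n", x$scheme,
              length(x$feature_names)))
  invisible(x)
}

## ---- multi-Gaussian --------------------------------------------------------

#' Fit the multi-Gaussian (MG) classifier
#'
#' Class-conditional multivariate Gaussians with diagonal covariance. Each
#' per-class variance is regularized as
#' `var_cj + epsilon + shrinkage * overall_var_j`, which floors zero-variance
#' features and shrinks small-sample estimates toward the pooled scale.
#' Scores are posterior probabilities `P(y = 1 | x)` from empirical class
#' priors and the class-conditional log-likelihoods.
#'
#' @param X numeric matrix (will be z-scored internally).
#' @param y 0/1 labels; at least 3 samples per class.
#' @param epsilon variance floor.
#' @param shrinkage shrinkage weight toward the overall per-feature variance.
#' @return fitted state for [mg_score()].
#' @export
mg_fit <- function(X, y, epsilon = 1e-6, shrinkage = 0.1) {
  X <- as.matrix(X)
  if (min(table(y)) < 3) stop("MG requires at least 3 samples per class")
  zs <- zscore_fit(X)
  Xz <- zscore_apply(X, zs)
  overall <- apply(Xz, 2, var)
  per_class <- lapply(c(0, 1), function(cls) {
    Xc <- Xz[y == cls, , drop = FALSE]
    list(mu = colMeans(Xc),
         sigma2 = apply(Xc, 2, var) + epsilon + shrinkage * overall,
         prior = mean(y == cls))
  })
  list(zs = zs, class0 = per_class[[1]], class1 = per_class[[2]])
}

mg_loglik <- function(cls, Xz) {
  # sum of independent Gaussian log densities per row
  n <- nrow(Xz)
  ll <- numeric(n)
  for (j in seq_len(ncol(Xz))) {
    ll <- ll + dnorm(Xz[, j], cls$mu[j], sqrt(cls$sigma2[j]), log = TRUE)
  }
  ll
}

#' Score with the multi-Gaussian classifier
#'
#' @param fit output of [mg_fit()].
#' @param X numeric matrix.
#' @return posterior `P(y = 1 | x)` per row.
#' @export
mg_score <- function(fit, X) {
  Xz <- zscore_apply(as.matrix(X), fit$zs)
  l0 <- mg_loglik(fit$class0, Xz) + log(fit$class0$prior)
  l1 <- mg_loglik(fit$class1, Xz) + log(fit$class1$prior)
  # normalized in log space for stability
  m <- pmax(l0, l1)
  exp(l1 - m) / (exp(l0 - m) + exp(l1 - m))
}

## ---- SVM (least-squares formulation, RBF kernel) ---------------------------

rbf_kernel <- function(A, B, gamma) exp(-gamma * euclidean_dist2(A, B))

svm_fit <- function(X, y, C = 1, gamma = "scale") {
  X <- as.matrix(X)
  zs <- zscore_fit(X)
  Xz <- zscore_apply(X, zs)
  if (identical(gamma, "scale")) {
    v <- mean(apply(Xz, 2, var))
    gamma <- 1 / (ncol(Xz) * max(v, 1e-12))
  }
  n <- nrow(Xz)
  ypm <- ifelse(y == 1, 1, -1)
  K <- rbf_kernel(Xz, Xz, gamma)
  # least-squares SVM system with bias:  [0 1'; 1 K + I/C] [b; alpha] = [0; y]
  A <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / C))
  sol <- solve(A, c(0, ypm))
  b <- sol[1]; alpha <- sol[-1]
  f_train <- as.numeric(K %*% alpha + b)
  # Platt-style calibration of decision values on the training set
  platt <- suppressWarnings(glm(y ~ f_train, family = binomial(),
                                control = list(maxit = 50)))
  list(zs = zs, gamma = gamma, alpha = alpha, b = b, Xsv = Xz,
       platt = coef(platt))
}

svm_score <- function(fit, X) {
  Xz <- zscore_apply(as.matrix(X), fit$zs)
  f <- as.numeric(rbf_kernel(Xz, fit$Xsv, fit$gamma) %*% fit$alpha + fit$b)
  eta <- fit$platt[1] + fit$platt[2] * f
  plogis(pmin(pmax(eta, -30), 30))
}

## ---- gradient boosting (XGB scheme) ----------------------------------------

xgb_fit <- function(X, y, n_rounds = 100, max_depth = 6, eta = 0.3,
                    lambda = 1, min_node = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  base <- log(max(mean(y), 1e-6) / max(1 - mean(y), 1e-6))
  margin <- rep(base, n)
  trees <- vector("list", n_rounds)
  for (t in seq_len(n_rounds)) {
    prob <- plogis(margin)
    g <- prob - y              # gradient of logistic loss
    h <- prob * (1 - prob)     # hessian
    tr <- cpp_fit_tree_gh(X, g, h, as.integer(max_depth),
                          as.integer(min_node), lambda)
    upd <- cpp_predict_tree(tr, X)
    if (all(abs(upd) < 1e-12)) { trees <- trees[seq_len(t - 1)]; break }
    margin <- margin + eta * upd
    trees[[t]] <- tr
  }
  list(base = base, eta = eta, trees = Filter(Negate(is.null), trees))
}

xgb_score <- function(fit, X) {
  X <- as.matrix(X)
  margin <- rep(fit$base, nrow(X))
  for (tr in fit$trees) margin <- margin + fit$eta * cpp_predict_tree(tr, X)
  plogis(margin)
}

## ---- neural network (single hidden layer, Adam) -----------------------------

nn_fit <- function(X, y, hidden = 32, epochs = 200, lr = 0.01, seed = 1) {
  X <- as.matrix(X)
  zs <- zscore_fit(X)
  Xz <- zscore_apply(X, zs)
  n <- nrow(Xz); p <- ncol(Xz)
  set.seed(seed)
  W1 <- matrix(rnorm(p * hidden, sd = sqrt(2 / p)), p, hidden)
  b1 <- rep(0, hidden)
  W2 <- matrix(rnorm(hidden, sd = sqrt(2 / hidden)), hidden, 1)
  b2 <- 0
  # Adam state
  mW1 <- vW1 <- W1 * 0; mb1 <- vb1 <- b1 * 0
  mW2 <- vW2 <- W2 * 0; mb2 <- vb2 <- 0
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  for (t in seq_len(epochs)) {
    H <- pmax(sweep(Xz %*% W1, 2, b1, "+"), 0)      # ReLU
    eta <- as.numeric(H %*% W2) + b2
    prob <- plogis(eta)
    d_eta <- (prob - y) / n                          # BCE gradient
    gW2 <- crossprod(H, d_eta)
    gb2 <- sum(d_eta)
    dH <- outer(d_eta, as.numeric(W2)) * (H > 0)
    gW1 <- crossprod(Xz, dH)
    gb1 <- colSums(dH)
    adam <- function(par, g, m, v) {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mh <- m / (1 - beta1^t); vh <- v / (1 - beta2^t)
      list(par = par - lr * mh / (sqrt(vh) + eps), m = m, v = v)
    }
    u <- adam(W1, gW1, mW1, vW1); W1 <- u$par; mW1 <- u$m; vW1 <- u$v
    u <- adam(b1, gb1, mb1, vb1); b1 <- u$par; mb1 <- u$m; vb1 <- u$v
    u <- adam(W2, gW2, mW2, vW2); W2 <- u$par; mW2 <- u$m; vW2 <- u$v
    u <- adam(b2, gb2, mb2, vb2); b2 <- u$par; mb2 <- u$m; vb2 <- u$v
  }
  list(zs = zs, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

nn_score <- function(fit, X) {
  Xz <- zscore_apply(as.matrix(X), fit$zs)
  H <- pmax(sweep(Xz %*% fit$W1, 2, fit$b1, "+"), 0)
  plogis(as.numeric(H %*% fit$W2) + fit$b2)
}
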