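#' Data-preparation method catalogue
#'
#' The eight operators, their category (OD outlier detection, FS feature
#' selection, DR dimensionality reduction, OS oversampling, US undersampling)
#' and their scope: feature-space steps (SFS, PCA) carry a fitted transform
#' that may legitimately be applied to unseen validation samples; sample-space
#' steps (resampling, removal) must stay confined to training data.
#'
#' @return data.frame with columns `method`, `category`, `scope`.
#' @export
mldp_methods <- function() {
  data.frame(
    method   = c("IF", "SFS", "PCA", "RO", "RU", "SMOTE", "BSMOTE", "TL"),
    category = c("OD", "FS", "DR", "OS", "US", "OS", "OS", "US"),
    scope    = c("sample_space", "feature_space", "feature_space",
                 "sample_space", "sample_space", "sample_space",
                 "sample_space", "sample_space"),
    stringsAsFactors = FALSE)
}

method_category <- function(method) {
  m <- mldp_methods()
  m$category[match(method, m$method)]
}

method_scope <- function(method) {
  m <- mldp_methods()
  m$scope[match(method, m$method)]
}

#' Hyperparameter registry
#'
#' Declared defaults and search bounds for every operator hyperparameter.
#' The originating study did not publish its ranges, so these are this
#' package's stated conventions (standard literature defaults); all tunable
#' entries are searchable by the evolutionary optimizer and overridable via
#' config.
#'
#' @return nested list: `registry[[method]][[param]]` with fields `default`,
#'   `lower`, `upper`, `integer`, `tunable`.
#' @export
hyperparam_registry <- function() {
  p <- function(default, lower = default, upper = default,
                integer = FALSE, tunable = FALSE) {
    list(default = default, lower = lower, upper = upper,
         integer = integer, tunable = tunable)
  }
  list(
    IF = list(
      n_trees = p(100, integer = TRUE),
      subsample_size = p(256, integer = TRUE),
      score_threshold = p(0.55, 0.5, 0.7, tunable = TRUE)),
    SFS = list(
      n_keep = p(10, 2, 30, integer = TRUE, tunable = TRUE),
      tol = p(1e-4)),
    PCA = list(
      variance_retained = p(0.95, 0.8, 0.99, tunable = TRUE)),
    RO = list(
      target_ratio = p(1.0, 0.5, 1.0, tunable = TRUE)),
    RU = list(
      target_ratio = p(1.0, 0.5, 1.0, tunable = TRUE)),
    SMOTE = list(
      k_neighbors = p(5, 1, 7, integer = TRUE, tunable = TRUE),
      target_ratio = p(1.0, 0.5, 1.0, tunable = TRUE)),
    BSMOTE = list(
      k_neighbors = p(5, 1, 7, integer = TRUE, tunable = TRUE),
      m_danger = p(10, integer = TRUE),
      target_ratio = p(1.0, 0.5, 1.0, tunable = TRUE)),
    TL = list())
}

default_hyperparams <- function(method, registry = hyperparam_registry()) {
  lapply(registry[[method]], `[[`, "default")
}

#' Specify one data-preparation step
#'
#' @param method one of `IF, SFS, PCA, RO, RU, SMOTE, BSMOTE, TL`.
#' @param hyperparams named list overriding registry defaults; with
#'   `check_bounds = TRUE` the values must lie within the declared bounds.
#' @param registry hyperparameter registry (see [hyperparam_registry()]).
#' @param check_bounds enforce the registry's search bounds. The bounds
#'   constrain the evolutionary optimizer; direct operator calls may step
#'   outside them (e.g. a diagnostic threshold of 1.0), so the operators
#'   record their specs unchecked.
#' @return object of class `prep_step`: list with `method`, `category`,
#'   `hyperparams`.
#' @export
prep_step <- function(method, hyperparams = list(),
                      registry = hyperparam_registry(), check_bounds = TRUE) {
  methods <- mldp_methods()$method
  if (!method %in% methods) {
    stop("unknown method_id '", method, "'; known: ", paste(methods, collapse = ", "))
  }
  hp <- default_hyperparams(method, registry)
  for (nm in names(hyperparams)) {
    if (!nm %in% names(hp)) stop("unknown hyperparameter '", nm, "' for ", method)
    spec <- registry[[method]][[nm]]
    v <- hyperparams[[nm]]
    if (check_bounds && (v < spec$lower || v > spec$upper)) {
      stop(sprintf("hyperparameter %s=%g outside bounds [%g, %g] for %s",
                   nm, v, spec$lower, spec$upper, method))
    }
    if (spec$integer) v <- as.integer(round(v))
    hp[[nm]] <- v
  }
  structure(list(method = method, category = method_category(method),
                 hyperparams = hp),
            class = "prep_step")
}

#' @export
format.prep_step <- function(x, ...) {
  reg <- hyperparam_registry()[[x$method]]
  tun <- names(reg)[vapply(reg, `[[`, logical(1), "tunable")]
  if (length(tun) == 0) return(x$method)
  vals <- vapply(tun, function(nm) {
    v <- x$hyperparams[[nm]]
    if (isTRUE(reg[[nm]]$integer)) sprintf("%s=%d", nm, as.integer(v))
    else sprintf("%s=%.3g", nm, v)
  }, character(1))
  sprintf("%s(%s)", x$method, paste(vals, collapse = ","))
}

#' @export
print.prep_step <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Build an ordered data-preparation pipeline
#'
#' @param ... `prep_step` objects or bare method-id strings (given defaults).
#' @return object of class `mldp_pipeline` (list of `prep_step`s).
#' @export
pipeline <- function(...) {
  steps <- lapply(list(...), function(s) {
    if (inherits(s, "prep_step")) s else prep_step(s)
  })
  structure(steps, class = "mldp_pipeline")
}

pipeline_methods <- function(pl) {
  vapply(unclass(pl), `[[`, character(1), "method")
}

#' @export
format.mldp_pipeline <- function(x, ...) {
  if (length(x) == 0) return("<empty pipeline>")
  paste(vapply(unclass(x), format, character(1)), collapse = " > ")
}

#' @export
print.mldp_pipeline <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
length.mldp_pipeline <- function(x) length(unclass(x))

# canonical cache/identity key: methods + rounded hyperparameters
pipeline_signature <- function(pl) {
  if (length(pl) == 0) return("<empty>")
  paste(vapply(unclass(pl), function(s) {
    hp <- s$hyperparams
    if (length(hp) == 0) return(s$method)
    paste0(s$method, "{",
           paste(sprintf("%s=%.6g", names(hp), unlist(hp)), collapse = ","), "}")
  }, character(1)), collapse = ">")
}
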