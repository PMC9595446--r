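#' Pipeline restriction table
#'
#' Clauses every admissible pipeline must satisfy: a method pool, a maximum
#' length, a per-method repetition cap (currently 1, i.e. no repetitions),
#' unordered method pairs that may not co-exist, and ordered pairs that may
#' not be consecutive.
#'
#' The default table uses all eight methods, maximum length 7, no
#' repetitions, and one mutual-exclusion pair `{SFS, PCA}` (both reshape the
#' feature space).
#'
#' @param method_pool character vector of method ids.
#' @param max_length maximum number of steps.
#' @param max_repetitions per-method occurrence cap (only 1 is supported).
#' @param forbidden_pairs list of length-2 character vectors (unordered).
#' @param forbidden_adjacencies list of length-2 character vectors (ordered:
#'   `c(a, b)` forbids `b` immediately after `a`).
#' @return object of class `restriction_table`.
#' @export
restriction_table <- function(method_pool = mldp_methods()$method,
                              max_length = 7, max_repetitions = 1,
                              forbidden_pairs = list(c("SFS", "PCA")),
                              forbidden_adjacencies = list()) {
  if (max_length < 1) stop("max_length must be >= 1")
  if (max_repetitions != 1) {
    stop("only max_repetitions = 1 (no repeats) is supported")
  }
  if (missing(forbidden_pairs)) {
    # the default pair only applies when the pool carries both members
    forbidden_pairs <- Filter(function(pr) all(pr %in% method_pool),
                              forbidden_pairs)
  }
  for (pr in c(forbidden_pairs, forbidden_adjacencies)) {
    if (!all(pr %in% method_pool)) {
      stop("forbidden pair/adjacency references methods outside the pool: ",
           paste(pr, collapse = ","))
    }
  }
  structure(list(method_pool = method_pool,
                 max_length = min(max_length, length(method_pool)),
                 max_repetitions = max_repetitions,
                 forbidden_pairs = forbidden_pairs,
                 forbidden_adjacencies = forbidden_adjacencies),
            class = "restriction_table")
}

#' Default restriction table
#' @return the default [restriction_table()].
#' @export
default_restrictions <- function() restriction_table()

#' Is an ordered method sequence a valid pipeline?
#'
#' @param steps an `mldp_pipeline` or a character vector of method ids
#'   (empty = empty pipeline, which is always valid).
#' @param restrictions a [restriction_table()].
#' @return logical.
#' @export
is_valid_pipeline <- function(steps, restrictions = default_restrictions()) {
  methods <- if (inherits(steps, "mldp_pipeline")) pipeline_methods(steps)
             else as.character(steps)
  if (length(methods) == 0) return(TRUE)
  # abstract pools (e.g. {A, B} in enumeration tests) extend the known set
  known <- union(mldp_methods()$method, restrictions$method_pool)
  unknown <- setdiff(methods, known)
  if (length(unknown) > 0) stop("unknown method_id: ", paste(unknown, collapse = ","))
  if (!all(methods %in% restrictions$method_pool)) return(FALSE)
  if (length(methods) > restrictions$max_length) return(FALSE)
  if (any(table(methods) > restrictions$max_repetitions)) return(FALSE)
  for (pr in restrictions$forbidden_pairs) {
    if (all(pr %in% methods)) return(FALSE)
  }
  if (length(methods) > 1) {
    for (ad in restrictions$forbidden_adjacencies) {
      for (i in seq_len(length(methods) - 1)) {
        if (methods[i] == ad[1] && methods[i + 1] == ad[2]) return(FALSE)
      }
    }
  }
  TRUE
}

# count the valid orderings of a given method subset (all k! when there are
# no adjacency clauses; DFS otherwise)
count_orderings <- function(subset, restrictions) {
  k <- length(subset)
  if (k <= 1 || length(restrictions$forbidden_adjacencies) == 0) {
    return(factorial(k))
  }
  cnt <- 0
  rec <- function(seq_so_far, remaining) {
    if (length(remaining) == 0) { cnt <<- cnt + 1; return(invisible()) }
    last <- if (length(seq_so_far)) seq_so_far[length(seq_so_far)] else NA
    for (m in remaining) {
      bad <- FALSE
      if (!is.na(last)) {
        for (ad in restrictions$forbidden_adjacencies) {
          if (last == ad[1] && m == ad[2]) { bad <- TRUE; break }
        }
      }
      if (!bad) rec(c(seq_so_far, m), setdiff(remaining, m))
    }
  }
  rec(character(0), subset)
  cnt
}

subset_allowed <- function(subset, restrictions) {
  for (pr in restrictions$forbidden_pairs) {
    if (all(pr %in% subset)) return(FALSE)
  }
  TRUE
}

#' Build the pipeline tree
#'
#' Enumeration structure of every restriction-satisfying pipeline: the root
#' is the empty pipeline and each root-to-node path is a valid ordered
#' pipeline (sequences with the same methods in different orders are distinct
#' nodes). Because all restriction clauses are hereditary (any prefix of a
#' valid pipeline is valid), the tree is summarized by its admissible method
#' subsets and per-depth node counts; full paths are materialized on demand
#' by [enumerate_pipelines()].
#'
#' @param restrictions a [restriction_table()].
#' @return object of class `mldp_pipeline_tree` with fields `restrictions`,
#'   `depth_counts` (named vector, depth 0 .. max_length) and `node_count`.
#' @export
build_pipeline_tree <- function(restrictions = default_restrictions()) {
  pool <- restrictions$method_pool
  if (length(pool) == 0) stop("method pool is empty")
  depth_counts <- numeric(restrictions$max_length + 1)
  names(depth_counts) <- 0:restrictions$max_length
  depth_counts["0"] <- 1
  subsets <- list()
  for (k in seq_len(restrictions$max_length)) {
    combs <- combn(pool, k, simplify = FALSE)
    keep <- Filter(function(s) subset_allowed(s, restrictions), combs)
    cnt <- sum(vapply(keep, count_orderings, numeric(1),
                      restrictions = restrictions))
    depth_counts[as.character(k)] <- cnt
    subsets[[k]] <- keep
  }
  structure(list(restrictions = restrictions, depth_counts = depth_counts,
                 node_count = sum(depth_counts), subsets = subsets),
            class = "mldp_pipeline_tree")
}

#' @export
print.mldp_pipeline_tree <- function(x, ...) {
  cat("<pipeline tree>", x$node_count, "nodes (incl. empty root)\n")
  cat("  per depth:", paste(sprintf("%s:%d", names(x$depth_counts),
                                    x$depth_counts), collapse = "  "), "\n")
  invisible(x)
}

#' Enumerate all valid pipelines of a tree
#'
#' @param tree an `mldp_pipeline_tree`.
#' @param lengths depths to materialize (default: all, including 0).
#' @return list of character vectors (method sequences; the empty pipeline is
#'   `character(0)`).
#' @export
enumerate_pipelines <- function(tree, lengths = NULL) {
  lengths <- lengths %||% 0:tree$restrictions$max_length
  out <- list()
  if (0 %in% lengths) out[[1]] <- character(0)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(rest) c(v[i], rest))
    }))
  }
  for (k in setdiff(lengths, 0)) {
    if (k > length(tree$subsets) || k < 1) next
    for (s in tree$subsets[[k]]) {
      for (pm in perms(s)) {
        if (is_valid_pipeline(pm, tree$restrictions)) {
          out[[length(out) + 1]] <- pm
        }
      }
    }
  }
  out
}

#' Sample a random valid pipeline from the tree
#'
#' Draws a length from `length_distribution` (uniform over available depths
#' by default, so short pipelines are not swamped by the combinatorial mass
#' of long ones), then a uniformly random valid pipeline of that length, and
#' attaches registry-default hyperparameters.
#'
#' @param tree an `mldp_pipeline_tree`.
#' @param length_distribution named numeric vector of probabilities over
#'   depths (names = depths as characters); default uniform over depths with
#'   at least one valid pipeline.
#' @param seed RNG seed.
#' @param max_retries bound on rejection-sampling retries per draw.
#' @return an `mldp_pipeline`.
#' @export
sample_pipeline <- function(tree, length_distribution = NULL, seed = 1,
                            max_retries = 1000) {
  avail <- tree$depth_counts[tree$depth_counts > 0]
  if (length(avail) <= 1) stop("tree is trivial: nothing to sample")
  ld <- length_distribution %||%
    setNames(rep(1 / length(avail), length(avail)), names(avail))
  ld <- ld[ld > 0]
  set.seed(seed)
  for (attempt in seq_len(max_retries)) {
    L <- as.integer(sample(names(ld), 1, prob = ld))
    if (L == 0) return(pipeline())
    if (tree$depth_counts[as.character(L)] == 0) next
    cand <- sample(tree$restrictions$method_pool, L)
    if (is_valid_pipeline(cand, tree$restrictions)) {
      return(do.call(pipeline, as.list(cand)))
    }
  }
  stop("failed to sample a valid pipeline after ", max_retries, " retries")
}
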