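#' Construct a labeled cohort
#'
#' The universal data container: a dense numeric feature matrix with one row
#' per patient/sample, a binary endpoint vector (1 = positive endpoint, e.g.
#' event or high risk) and unique sample/feature identifiers.
#'
#' @param X numeric matrix, `n_samples x n_features`, all values finite.
#' @param y binary label vector, values in `{0, 1}`.
#' @param sample_ids character vector of unique sample identifiers
#'   (default `"s1" ...`).
#' @param feature_names character vector of unique feature names (default
#'   taken from `colnames(X)` or `"f1" ...`).
#' @param positive_label_name display name of the positive class.
#' @param negative_label_name display name of the negative class.
#' @param provenance free-text tag, e.g. `"synthetic-seed42"`.
#' @param require_both_classes error if only one class is present (any cohort
#'   used for training must carry both).
#' @return an object of class `labeled_cohort`: a list with elements
#'   `X`, `y`, `sample_ids`, `feature_names`, `positive_label_name`,
#'   `negative_label_name`, `provenance`.
#' @export
labeled_cohort <- function(X, y, sample_ids = NULL, feature_names = NULL,
                           positive_label_name = "1",
                           negative_label_name = "0",
                           provenance = "", require_both_classes = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.integer(y)
  if (nrow(X) != length(y)) {
    stop("row count of X (", nrow(X), ") must equal length of y (", length(y), ")")
  }
  if (!all(y %in% c(0L, 1L))) stop("y must contain only values in {0, 1}")
  if (any(!is.finite(X))) stop("X contains NaN/Inf/missing entries")
  sample_ids <- sample_ids %||% paste0("s", seq_len(nrow(X)))
  feature_names <- feature_names %||% colnames(X) %||% paste0("f", seq_len(ncol(X)))
  if (length(sample_ids) != nrow(X)) stop("sample_ids length must match nrow(X)")
  if (length(feature_names) != ncol(X)) stop("feature_names length must match ncol(X)")
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (anyDuplicated(feature_names)) stop("feature_names must be unique")
  if (require_both_classes && length(unique(y)) < 2L) {
    stop("degenerate cohort: only one class present in y")
  }
  rownames(X) <- sample_ids
  colnames(X) <- feature_names
  structure(
    list(X = X, y = y, sample_ids = as.character(sample_ids),
         feature_names = as.character(feature_names),
         positive_label_name = positive_label_name,
         negative_label_name = negative_label_name,
         provenance = provenance),
    class = "labeled_cohort")
}

#' @export
print.labeled_cohort <- function(x, ...) {
  ir <- imbalance_ratio(x)
  cat(sprintf("<labeled_cohort> %d samples x %d features, imbalance %s%s\n",
              nrow(x$X), ncol(x$X), format(ir),
              if (nzchar(x$provenance)) paste0(" [", x$provenance, "]") else ""))
  invisible(x)
}

#' @export
dim.labeled_cohort <- function(x) dim(x$X)

# keep a row subset, preserving ids and labels
subset_cohort <- function(cohort, rows, require_both_classes = FALSE) {
  labeled_cohort(cohort$X[rows, , drop = FALSE], cohort$y[rows],
                 sample_ids = cohort$sample_ids[rows],
                 feature_names = cohort$feature_names,
                 positive_label_name = cohort$positive_label_name,
                 negative_label_name = cohort$negative_label_name,
                 provenance = cohort$provenance,
                 require_both_classes = require_both_classes)
}

# replace the feature block (feature-space transforms), keeping samples
replace_features <- function(cohort, X, feature_names) {
  labeled_cohort(X, cohort$y, sample_ids = cohort$sample_ids,
                 feature_names = feature_names,
                 positive_label_name = cohort$positive_label_name,
                 negative_label_name = cohort$negative_label_name,
                 provenance = cohort$provenance,
                 require_both_classes = FALSE)
}

detect_delimiter <- function(path) {
  header <- readLines(path, n = 1L)
  counts <- c("," = lengths(regmatches(header, gregexpr(",", header, fixed = TRUE))),
              ";" = lengths(regmatches(header, gregexpr(";", header, fixed = TRUE))),
              "\t" = lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE))))
  if (all(counts == 0)) stop("could not detect a delimiter (comma/semicolon/tab) in ", path)
  names(counts)[which.max(counts)]
}

#' Read a labeled cohort from a delimited text file
#'
#' One sample per row, a mandatory header, numeric feature columns, one label
#' column and an optional id column. The delimiter is auto-detected among
#' comma, semicolon and tab unless given. Rows with missing feature values
#' are rejected (dropped with a warning): imputation would amount to an
#' undeclared preparation step.
#'
#' @param path file path.
#' @param label_column name of the endpoint column.
#' @param positive_value label value mapped to `y = 1`.
#' @param id_column optional name of a sample-id column.
#' @param delimiter optional explicit delimiter.
#' @param provenance provenance tag stored on the cohort.
#' @return a [labeled_cohort()].
#' @export
read_cohort <- function(path, label_column, positive_value, id_column = NULL,
                        delimiter = NULL, provenance = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  delimiter <- delimiter %||% detect_delimiter(path)
  df <- read.table(path, header = TRUE, sep = delimiter,
                   colClasses = "character", check.names = FALSE,
                   na.strings = c("NA", ""), quote = "\"",
                   comment.char = "")
  if (!label_column %in% names(df)) {
    stop("schema error: label column '", label_column, "' not found; columns are: ",
         paste(names(df), collapse = ", "))
  }
  if (!is.null(id_column) && !id_column %in% names(df)) {
    stop("schema error: id column '", id_column, "' not found")
  }
  labels <- df[[label_column]]
  ids <- if (is.null(id_column)) paste0("s", seq_len(nrow(df))) else df[[id_column]]
  feat_cols <- setdiff(names(df), c(label_column, id_column))
  if (length(feat_cols) == 0) stop("no feature columns present")
  Xc <- df[feat_cols]
  Xn <- suppressWarnings(vapply(Xc, as.numeric, numeric(nrow(df))))
  Xn <- matrix(Xn, nrow = nrow(df), dimnames = list(NULL, feat_cols))
  # a cell that is present but not numeric is a parse error; name it
  bad <- which(is.na(Xn) & !is.na(as.matrix(Xc)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("parse error: non-numeric value '%s' at row %d, column '%s'",
                 Xc[[bad[1, 2]]][bad[1, 1]], bad[1, 1], feat_cols[bad[1, 2]]))
  }
  miss_rows <- which(rowSums(is.na(Xn)) > 0 | is.na(labels))
  if (length(miss_rows) > 0) {
    warning("rejecting ", length(miss_rows), " sample(s) with missing values: ",
            paste(utils::head(ids[miss_rows], 5), collapse = ", "),
            if (length(miss_rows) > 5) ", ..." else "")
    keep <- setdiff(seq_len(nrow(Xn)), miss_rows)
    Xn <- Xn[keep, , drop = FALSE]
    labels <- labels[keep]
    ids <- ids[keep]
  }
  y <- as.integer(labels == positive_value)
  neg <- unique(labels[y == 0])
  if (length(unique(y)) < 2L) {
    stop("degenerate cohort: label column has a single class after binarization ",
         "(positive_value = '", positive_value, "')")
  }
  labeled_cohort(Xn, y, sample_ids = ids, feature_names = feat_cols,
                 positive_label_name = as.character(positive_value),
                 negative_label_name = as.character(neg[1]),
                 provenance = provenance)
}

#' Write a labeled cohort to a delimited text file
#'
#' Inverse of [read_cohort()]: values are written with 17 significant digits
#' so a read/write round trip reproduces the matrix to within floating-point
#' text precision.
#'
#' @param cohort a [labeled_cohort()].
#' @param path output path.
#' @param delimiter field delimiter (default comma).
#' @param label_column,id_column column names used in the output.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, delimiter = ",",
                         label_column = "label", id_column = "sample_id") {
  labels <- ifelse(cohort$y == 1, cohort$positive_label_name,
                   cohort$negative_label_name)
  Xchr <- apply(cohort$X, 2, function(col) sprintf("%.17g", col))
  if (is.null(dim(Xchr))) Xchr <- matrix(Xchr, nrow = nrow(cohort$X))
  df <- data.frame(id = cohort$sample_ids, Xchr, lab = labels,
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c(id_column, cohort$feature_names, label_column)
  ok <- tryCatch({
    write.table(df, path, sep = delimiter, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("I/O error writing '", path, "': ", conditionMessage(ok))
  invisible(path)
}

#' Majority-vs-minority class percentages of a cohort
#'
#' @param cohort a [labeled_cohort()], or a bare 0/1 vector.
#' @return an object of class `imbalance_ratio` with fields `majority_pct`,
#'   `minority_pct` (rounded to integers for reporting) and their exact
#'   counterparts.
#' @export
imbalance_ratio <- function(cohort) {
  y <- if (inherits(cohort, "labeled_cohort")) cohort$y else as.integer(cohort)
  if (length(y) == 0) stop("empty cohort")
  pct1 <- 100 * mean(y == 1)
  pct0 <- 100 - pct1
  maj <- max(pct0, pct1)
  mino <- min(pct0, pct1)
  structure(list(majority_pct = round(maj), minority_pct = round(mino),
                 majority_pct_exact = maj, minority_pct_exact = mino,
                 majority_class = if (pct0 >= pct1) 0L else 1L),
            class = "imbalance_ratio")
}

#' @export
format.imbalance_ratio <- function(x, ...) {
  sprintf("%d-vs-%d", x$majority_pct, x$minority_pct)
}

#' @export
print.imbalance_ratio <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
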