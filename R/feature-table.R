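# Feature tables: tibbles of samples x features with one label column.

#' Validate a feature table
#'
#' Checks the contract every downstream stage relies on: a label column is
#' present, all other columns are finite numerics, and every class has at
#' least two samples (needed for stratified cross-validation).
#'
#' @param data Data frame of numeric features plus one label column.
#' @param label_col Name of the label column; default `"label"`.
#' @return List with `x` (numeric matrix), `y` (factor), `features`
#'   (column names).
#' @export
validate_features <- function(data, label_col = "label") {
  if (!is.data.frame(data)) stop("data must be a data frame", call. = FALSE)
  if (!label_col %in% names(data)) {
    stop(sprintf("label column '%s' not found", label_col), call. = FALSE)
  }
  feats <- setdiff(names(data), label_col)
  if (length(feats) < 1) stop("no feature columns", call. = FALSE)
  x <- as.matrix(data[feats])
  if (!is.numeric(x)) stop("feature columns must be numeric", call. = FALSE)
  if (anyNA(x) || !all(is.finite(x))) {
    stop("feature table contains NA or non-finite values", call. = FALSE)
  }
  y <- droplevels(as.factor(data[[label_col]]))
  if (nlevels(y) < 2) stop("need at least two classes", call. = FALSE)
  if (min(table(y)) < 2) {
    stop("every class needs at least two samples", call. = FALSE)
  }
  list(x = x, y = y, features = feats)
}

#' Read / write a delimited feature table
#'
#' Comma-separated UTF-8 text with a header row of feature names and one
#' label column; the on-disk format every pipeline stage exchanges.
#'
#' @param path File path.
#' @param label_col Name of the label column (checked on read).
#' @return A tibble.
#' @export
read_feature_table <- function(path, label_col = "label") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  if (!label_col %in% names(df)) {
    stop(sprintf("label column '%s' not found in %s", label_col, path),
         call. = FALSE)
  }
  df
}

#' @param data Data frame to write.
#' @rdname read_feature_table
#' @export
write_feature_table <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}
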