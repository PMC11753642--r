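# Serial feature fusion: array-based concatenation of two feature tables.

#' Fuse two feature tables by serial concatenation
#'
#' Concatenates the feature columns of `x` followed by those of `y` for the
#' same samples, leaving values untouched: the fused width is `d1 + d2`.
#' Alignment is enforced — row counts must match, and when an `id_col` is
#' present in both tables the ids must agree row by row (the first offending
#' row is named). Labels, when present in both, must also agree.
#'
#' @param x,y Data frames of features, optionally with a label column and a
#'   sample-id column.
#' @param label_col Name of the label column (kept once in the output);
#'   default `"label"`. Set `NULL` if there is none.
#' @param id_col Optional sample-id column checked row-wise and kept once.
#' @param standardize If `TRUE`, each feature column is centered and scaled
#'   to unit variance before concatenation (off by default: plain serial
#'   fusion does not rescale).
#' @return A tibble of class `fused_features`; per-column provenance is
#'   available via [fusion_provenance()].
#' @examples
#' a <- tibble::tibble(f1 = 1:3, f2 = 4:6, label = c("a", "b", "a"))
#' b <- tibble::tibble(g1 = 7:9, label = c("a", "b", "a"))
#' fuse_features(a, b)
#' @export
fuse_features <- function(x, y, label_col = "label", id_col = NULL,
                          standardize = FALSE) {
  stopifnot(is.data.frame(x), is.data.frame(y))
  if (nrow(x) != nrow(y)) {
    stop(sprintf("row-count mismatch: %d vs %d rows", nrow(x), nrow(y)),
         call. = FALSE)
  }
  meta <- character(0)
  if (!is.null(id_col) && id_col %in% names(x) && id_col %in% names(y)) {
    mism <- which(as.character(x[[id_col]]) != as.character(y[[id_col]]))
    if (length(mism) > 0) {
      stop(sprintf("sample-id mismatch at row %d ('%s' vs '%s')", mism[1],
                   x[[id_col]][mism[1]], y[[id_col]][mism[1]]), call. = FALSE)
    }
    meta <- c(meta, id_col)
  }
  if (!is.null(label_col) && label_col %in% names(x) &&
      label_col %in% names(y)) {
    if (!identical(as.character(x[[label_col]]),
                   as.character(y[[label_col]]))) {
      stop("label columns disagree between the two tables", call. = FALSE)
    }
    meta <- c(meta, label_col)
  } else if (!is.null(label_col) && label_col %in% names(x)) {
    meta <- c(meta, label_col)
  } else if (!is.null(label_col) && label_col %in% names(y)) {
    meta <- c(meta, label_col)
  }
  f1 <- setdiff(names(x), meta)
  f2 <- setdiff(names(y), meta)
  v1 <- x[f1]
  v2 <- y[f2]
  if (standardize) {
    std <- function(df) dplyr::mutate(df, dplyr::across(
      dplyr::everything(),
      function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v - mean(v)))
    v1 <- std(v1)
    v2 <- std(v2)
  }
  out1 <- f1
  out2 <- f2
  clash <- intersect(out2, out1)
  if (length(clash) > 0) {
    out2[match(clash, out2)] <- paste0(clash, "_2")
    names(v2) <- out2
  }
  metadf <- if (length(meta) > 0) {
    src <- if (all(meta %in% names(x))) x else y
    src[intersect(meta, names(src))]
  } else NULL
  fused <- tibble::as_tibble(dplyr::bind_cols(
    c(if (!is.null(metadf)) list(metadf), list(v1), list(v2)),
    .name_repair = "minimal"))
  prov <- tibble::tibble(
    column = c(out1, out2),
    source = rep(c("vec1", "vec2"), c(length(f1), length(f2))),
    original_index = c(seq_along(f1), seq_along(f2)),
    original_name = c(f1, f2))
  attr(fused, "provenance") <- prov
  class(fused) <- c("fused_features", class(fused))
  fused
}

#' Per-column provenance of a fused table
#'
#' @param x A `fused_features` tibble.
#' @return Tibble mapping each fused column to its source table
#'   (`vec1`/`vec2`), original index and original name.
#' @export
fusion_provenance <- function(x) {
  prov <- attr(x, "provenance")
  if (is.null(prov)) stop("no provenance attribute; not a fused table",
                          call. = FALSE)
  prov
}

#' Split a fused table back into its two source tables
#'
#' Inverse of [fuse_features()] up to column naming: values round-trip
#' bit-exactly.
#'
#' @param x A `fused_features` tibble.
#' @return List with `vec1` and `vec2` tibbles (original column names).
#' @export
unfuse_features <- function(x) {
  prov <- fusion_provenance(x)
  take <- function(src) {
    p <- prov[prov$source == src, ]
    cols <- lapply(p$column, function(cn) x[[cn]])
    tibble::as_tibble(stats::setNames(cols, p$original_name))
  }
  list(vec1 = take("vec1"), vec2 = take("vec2"))
}

#' Write fused features with a provenance sidecar
#'
#' The table goes to `path` as CSV; provenance to `<path>.provenance.json`.
#'
#' @param x A `fused_features` tibble.
#' @param path Output CSV path.
#' @export
write_fused_features <- function(x, path) {
  write_feature_table(x, path)
  jsonlite::write_json(fusion_provenance(x),
                       paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
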