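# Multiclass evaluation metrics.
#
# All rates are expressed in percent and derived from a K x K confusion
# matrix read one-vs-rest: for class k, TP is the diagonal entry, FN the
# rest of its row, FP the rest of its column, TN everything else. A metric
# whose denominator is zero is reported as NA (undefined) rather than
# coerced to 0, so tiny test folds cannot silently inflate averages.

#' Confusion matrix from true and predicted labels
#'
#' @param truth,estimate Vectors of equal length; factors or coercible.
#' @param levels Optional class levels. Defaults to the union of levels of
#'   `truth` and `estimate`; an `estimate` label outside the levels of
#'   `truth` when `levels` is given is an error.
#' @return Integer matrix of class `confusion_matrix`; rows are true
#'   classes, columns predicted classes.
#' @examples
#' confusion_matrix(c(1, 1, 2), c(1, 2, 2))
#' @export
confusion_matrix <- function(truth, estimate, levels = NULL) {
  if (length(truth) != length(estimate)) {
    stop("truth and estimate must have equal length", call. = FALSE)
  }
  if (is.null(levels)) {
    levels <- sort(unique(c(as.character(truth), as.character(estimate))))
  } else {
    bad <- setdiff(unique(c(as.character(truth), as.character(estimate))),
                   as.character(levels))
    if (length(bad) > 0) {
      stop("labels outside the declared levels: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  t_f <- factor(as.character(truth), levels = levels)
  e_f <- factor(as.character(estimate), levels = levels)
  cm <- table(t_f, e_f, dnn = c("truth", "estimate"))
  structure(unclass(cm), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> rows = truth, cols = estimate\n")
  print(unclass(x))
  invisible(x)
}

pct <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)

#' F1 score from precision and recall (percent scale)
#'
#' Harmonic mean `2 P R / (P + R)`; `NA` if either input is undefined or
#' both are zero.
#'
#' @param precision,recall Percentages.
#' @export
f1_score <- function(precision, recall) {
  ifelse(is.na(precision) | is.na(recall) | (precision + recall) == 0,
         NA_real_, 2 * precision * recall / (precision + recall))
}

#' Per-class and macro metrics from a confusion matrix
#'
#' One-vs-rest recall (sensitivity), precision, F1, false-negative rate and
#' false-positive rate per class, plus unweighted macro averages and overall
#' accuracy, all in percent. Identities that hold exactly: recall + FNR =
#' 100 per class; accuracy = 100 * trace / total; F1 is the harmonic mean of
#' that class's precision and recall.
#'
#' @param cm A [confusion_matrix()] (any square numeric matrix works).
#' @return An object of class `metrics_report` with `per_class` (tibble),
#'   `macro` (named list), and `accuracy`.
#' @export
per_class_metrics <- function(cm) {
  cm <- unclass(as.matrix(cm))
  stopifnot(nrow(cm) == ncol(cm))
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix", call. = FALSE)
  classes <- rownames(cm) %||% as.character(seq_len(nrow(cm)))
  tp <- unname(diag(cm))
  fn <- unname(rowSums(cm)) - tp
  fp <- unname(colSums(cm)) - tp
  tn <- total - tp - fn - fp
  recall <- pct(tp, tp + fn)
  precision <- pct(tp, tp + fp)
  per_class <- tibble::tibble(
    class = classes,
    support = as.integer(unname(rowSums(cm))),
    tp = as.integer(tp), fp = as.integer(fp),
    fn = as.integer(fn), tn = as.integer(tn),
    recall = recall,
    precision = precision,
    f1 = f1_score(precision, recall),
    fnr = ifelse(is.na(recall), NA_real_, 100 - recall),
    fpr = pct(fp, fp + tn)
  )
  macro <- list(recall = macro_average(per_class$recall),
                precision = macro_average(per_class$precision),
                f1 = macro_average(per_class$f1),
                fnr = macro_average(per_class$fnr),
                fpr = macro_average(per_class$fpr))
  structure(list(per_class = per_class, macro = macro,
                 accuracy = 100 * sum(tp) / total,
                 n = as.integer(total),
                 n_undefined = sum(is.na(per_class$recall)) +
                   sum(is.na(per_class$precision))),
            class = "metrics_report")
}

#' Macro (unweighted) average of per-class values
#'
#' Mean of the defined (non-`NA`) values; `NA` if none are defined.
#'
#' @param x Numeric vector of per-class metric values.
#' @examples
#' macro_average(c(98.2, 100, 100, 97.1, 100)) # 99.06
#' @export
macro_average <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) NA_real_ else mean(x)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d samples, %d classes, accuracy %.2f%%\n",
              x$n, nrow(x$per_class), x$accuracy))
  cat(sprintf("  macro: recall %.2f  precision %.2f  F1 %.2f  FNR %.2f\n",
              x$macro$recall, x$macro$precision, x$macro$f1, x$macro$fnr))
  if (x$n_undefined > 0) {
    cat(sprintf("  (%d undefined per-class values excluded from macros)\n",
                x$n_undefined))
  }
  invisible(x)
}

#' Tidy per-class metrics
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' One-row summary of a metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy,
                 macro_recall = x$macro$recall,
                 macro_precision = x$macro$precision,
                 macro_f1 = x$macro$f1,
                 macro_fnr = x$macro$fnr,
                 n = x$n)
}

#' Confusion-matrix heatmap
#'
#' @param object A `confusion_matrix`.
#' @param ... Unused.
#' @method autoplot confusion_matrix
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(as.matrix(object))))
  names(df) <- c("truth", "estimate", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "Predicted", y = "True", title = "Confusion matrix") +
    ggplot2::theme_minimal()
}

# ---- evaluation protocol ---------------------------------------------------

# Stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin to folds.
stratified_folds <- function(y, k) {
  y <- as.factor(y)
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Evaluate a classifier preset under a holdout + cross-validation protocol
#'
#' Splits the data into a stratified train/test partition (default 80:20),
#' then reports two clearly separated surfaces: k-fold cross-validated
#' metrics on the training partition, and metrics on the held-out test
#' partition fitted on the full training partition. The two are never mixed.
#'
#' @param data Data frame of features plus one label column.
#' @param spec A [classifier_spec()] or preset id string.
#' @param label_col Name of the label column; default `"label"`.
#' @param holdout_fraction Fraction held out for testing; default 0.2.
#' @param cv_folds Folds for the CV surface; default 10.
#' @param seed Seed driving the split and fold assignment.
#' @return Object of class `classifier_evaluation` with `$holdout` and
#'   `$cv` (both [per_class_metrics()] reports), `$wall_time` (seconds,
#'   informational), and the echoed protocol.
#' @export
evaluate_classifier <- function(data, spec, label_col = "label",
                                holdout_fraction = 0.2, cv_folds = 10,
                                seed = 1L) {
  if (is.character(spec)) spec <- classifier_spec(spec, seed = seed)
  fm <- validate_features(data, label_col)
  t0 <- proc.time()[["elapsed"]]
  res <- withr::with_seed(seed, {
    n <- nrow(fm$x)
    test_idx <- which(stratified_folds(fm$y, round(1 / holdout_fraction)) == 1)
    train_idx <- setdiff(seq_len(n), test_idx)
    y_tr <- droplevels(fm$y[train_idx])
    if (nlevels(y_tr) < nlevels(droplevels(fm$y))) {
      stop("a class is absent from the training partition", call. = FALSE)
    }
    # CV surface on the training partition
    cv_pred <- cv_predict(fm$x[train_idx, , drop = FALSE], y_tr, spec, cv_folds)
    cv_report <- per_class_metrics(confusion_matrix(y_tr, cv_pred,
                                                    levels = levels(y_tr)))
    # holdout surface
    model <- fit_classifier(spec, fm$x[train_idx, , drop = FALSE], y_tr)
    pred <- predict_classifier(model, fm$x[test_idx, , drop = FALSE])
    holdout_report <- per_class_metrics(
      confusion_matrix(fm$y[test_idx], pred, levels = levels(y_tr)))
    list(cv = cv_report, holdout = holdout_report)
  })
  structure(list(holdout = res$holdout, cv = res$cv,
                 wall_time = proc.time()[["elapsed"]] - t0,
                 spec = spec,
                 protocol = list(holdout_fraction = holdout_fraction,
                                 cv_folds = cv_folds, seed = seed)),
            class = "classifier_evaluation")
}

# k-fold CV predictions on (x, y); re-stratifies once if a fold's training
# partition loses a class, then fails loudly.
cv_predict <- function(x, y, spec, k) {
  for (attempt in 1:2) {
    folds <- stratified_folds(y, k)
    ok <- all(vapply(seq_len(k), function(f) {
      nlevels(droplevels(y[folds != f])) == nlevels(y)
    }, logical(1)))
    if (ok) break
    if (attempt == 2) {
      stop("a class is absent from a cross-validation fold", call. = FALSE)
    }
  }
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (f in seq_len(k)) {
    tr <- folds != f
    if (!any(!tr)) next
    model <- fit_classifier(spec, x[tr, , drop = FALSE], droplevels(y[tr]))
    pred[!tr] <- predict_classifier(model, x[!tr, , drop = FALSE])
  }
  pred
}

#' @export
print.classifier_evaluation <- function(x, ...) {
  cat(sprintf("<classifier_evaluation> preset %s\n", x$spec$preset))
  cat(sprintf("  holdout (%.0f%%): accuracy %.2f%%\n",
              100 * x$protocol$holdout_fraction, x$holdout$accuracy))
  cat(sprintf("  %d-fold CV on train: accuracy %.2f%%\n",
              x$protocol$cv_folds, x$cv$accuracy))
  invisible(x)
}

#' Tidy a classifier evaluation
#'
#' @param x A `classifier_evaluation`.
#' @param surface `"holdout"` (default) or `"cv"`.
#' @param ... Unused.
#' @return Per-class metric tibble with a `surface` column.
#' @method tidy classifier_evaluation
#' @export
tidy.classifier_evaluation <- function(x, surface = c("holdout", "cv"), ...) {
  surface <- match.arg(surface)
  dplyr::mutate(x[[surface]]$per_class, surface = surface, .before = 1)
}

#' One-row summary of a classifier evaluation
#'
#' @param x A `classifier_evaluation`.
#' @param ... Unused.
#' @method glance classifier_evaluation
#' @export
glance.classifier_evaluation <- function(x, ...) {
  tibble::tibble(preset = x$spec$preset,
                 holdout_accuracy = x$holdout$accuracy,
                 cv_accuracy = x$cv$accuracy,
                 macro_recall = x$holdout$macro$recall,
                 macro_precision = x$holdout$macro$precision,
                 macro_f1 = x$holdout$macro$f1,
                 wall_time = x$wall_time)
}

#' Report table in the conventional column layout
#'
#' One row per evaluation, columns Recall, Precision, FNR, Time, F1,
#' Accuracy (percent; time in seconds), the layout used in the disease
#' classification literature this package serves.
#'
#' @param ... `classifier_evaluation` objects (or a single list of them).
#' @param surface `"holdout"` or `"cv"`.
#' @export
report_table <- function(..., surface = c("holdout", "cv")) {
  surface <- match.arg(surface)
  evals <- list(...)
  if (length(evals) == 1 && !inherits(evals[[1]], "classifier_evaluation")) {
    evals <- evals[[1]]
  }
  purrr::map_dfr(evals, function(ev) {
    rep <- ev[[surface]]
    tibble::tibble(classifier = ev$spec$preset,
                   recall = rep$macro$recall,
                   precision = rep$macro$precision,
                   fnr = rep$macro$fnr,
                   time = ev$wall_time,
                   f1 = rep$macro$f1,
                   accuracy = rep$accuracy)
  })
}
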