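# Wrapper feature selection by binary MFO.
#
# The optimizer searches the continuous cube [0,1]^d; positions are
# thresholded at 0.5 into boolean column masks, and each mask is scored by
# stratified cross-validated classifier error plus a small subset-size
# penalty:
#
#   fitness(mask) = alpha * cv_error(mask) + (1 - alpha) * |mask| / d
#
# With alpha near 1 the classifier error dominates and the size term only
# breaks ties toward smaller subsets. Fold assignment is a pure function of
# the fitness seed, so fitness is deterministic in (mask, data, spec) and
# repeated masks are memoized within a run.

#' Fitness specification for wrapper selection
#'
#' @param alpha Weight of the cross-validated error term, in (0, 1];
#'   default 0.99. The remaining `1 - alpha` weights the selected-fraction
#'   penalty.
#' @param inner_classifier Preset id scoring candidate subsets; default
#'   `"f_knn"` (1-nearest-neighbor: fast and parameter-free).
#' @param cv_folds Stratified folds for the inner error estimate; default 5.
#' @param seed Seed fixing the fold assignment.
#' @return An object of class `fitness_spec`.
#' @export
fitness_spec <- function(alpha = 0.99, inner_classifier = "f_knn",
                         cv_folds = 5, seed = 1L) {
  stopifnot(alpha > 0, alpha <= 1, cv_folds >= 2)
  structure(list(alpha = alpha,
                 inner_classifier = normalize_preset(inner_classifier),
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "fitness_spec")
}

#' Threshold a continuous position into a feature mask
#'
#' `mask[j] = position[j] > 0.5`. An all-false mask is repaired by selecting
#' the coordinate with the largest position (lowest index on ties), keeping
#' the search space closed under binarization.
#'
#' @param position Numeric vector in `[0, 1]^d`.
#' @return Logical vector with at least one `TRUE`.
#' @examples
#' binarize_position(c(0.1, 0.3, 0.2)) # repair selects index 2
#' @export
binarize_position <- function(position) {
  if (anyNA(position) || !all(is.finite(position))) {
    stop("position contains non-finite values", call. = FALSE)
  }
  mask <- position > 0.5
  if (!any(mask)) mask[which.max(position)] <- TRUE
  mask
}

# Build the memoized fitness evaluator. For the default 1-NN inner
# classifier, per-feature squared-difference matrices are precomputed once
# (an n^2 x d matrix), so a mask's distance matrix is a single
# matrix-vector product; other presets go through fit/predict per fold.
make_fitness_evaluator <- function(data, label_col, spec) {
  fm <- validate_features(data, label_col)
  n <- nrow(fm$x)
  d <- ncol(fm$x)
  folds <- withr::with_seed(spec$seed, stratified_folds(fm$y, spec$cv_folds))
  for (f in seq_len(spec$cv_folds)) {
    if (nlevels(droplevels(fm$y[folds == f])) < nlevels(fm$y) ||
        nlevels(droplevels(fm$y[folds != f])) < nlevels(fm$y)) {
      stop("a class is absent from a cross-validation fold; ",
           "reduce cv_folds or add samples", call. = FALSE)
    }
  }
  fast_1nn <- spec$inner_classifier == "f_knn"
  if (fast_1nn) {
    # sqdiff[(i-1)*n + j, k] = (x[i,k] - x[j,k])^2
    sqdiff <- matrix(0, n * n, d)
    for (k in seq_len(d)) {
      dk <- outer(fm$x[, k], fm$x[, k], `-`)
      sqdiff[, k] <- as.numeric(dk * dk)
    }
  }
  memo <- new.env(parent = emptyenv())
  cv_error <- function(mask) {
    if (fast_1nn) {
      dist2 <- matrix(sqdiff %*% mask, n, n)
      correct <- 0L
      for (f in seq_len(spec$cv_folds)) {
        te <- which(folds == f)
        tr <- which(folds != f)
        block <- dist2[te, tr, drop = FALSE]
        pred <- fm$y[tr][max.col(-block, ties.method = "first")]
        correct <- correct + sum(pred == fm$y[te])
      }
      1 - correct / n
    } else {
      cspec <- classifier_spec(spec$inner_classifier, seed = spec$seed)
      correct <- 0L
      xsub <- fm$x[, mask, drop = FALSE]
      for (f in seq_len(spec$cv_folds)) {
        te <- folds == f
        model <- fit_classifier(cspec, xsub[!te, , drop = FALSE],
                                droplevels(fm$y[!te]))
        pred <- predict_classifier(model, xsub[te, , drop = FALSE])
        correct <- correct + sum(pred == fm$y[te])
      }
      1 - correct / n
    }
  }
  evaluate <- function(mask) {
    key <- paste(which(mask), collapse = ",")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    err <- cv_error(mask)
    out <- list(cv_error = err,
                fitness = spec$alpha * err +
                  (1 - spec$alpha) * sum(mask) / d)
    memo[[key]] <- out
    out
  }
  list(evaluate = evaluate, d = d, features = fm$features)
}

#' Fitness of a feature mask
#'
#' `alpha * cv_error + (1 - alpha) * n_selected / d`, with the error term
#' the stratified `cv_folds`-fold error of the inner classifier restricted
#' to the masked columns. Deterministic in `(mask, data, spec)`.
#'
#' @param mask Logical vector over the feature columns (at least one `TRUE`).
#' @param data Feature table (data frame with a label column).
#' @param label_col Name of the label column.
#' @param spec A [fitness_spec()].
#' @return Scalar fitness (smaller is better).
#' @export
selection_fitness <- function(mask, data, label_col = "label",
                              spec = fitness_spec()) {
  ev <- make_fitness_evaluator(data, label_col, spec)
  if (length(mask) != ev$d) stop("mask length does not match feature count",
                                 call. = FALSE)
  if (!any(mask)) stop("mask selects no feature", call. = FALSE)
  ev$evaluate(as.logical(mask))$fitness
}

#' Select features by binary Moth-Flame Optimization
#'
#' Runs [mfo_optimize()] over `[0,1]^d` with the wrapper fitness above and
#' returns the best mask found, its cross-validated error, and the full
#' convergence trace. Identical seeds reproduce identical selections.
#'
#' @param data Feature table (data frame with a label column).
#' @param label_col Name of the label column; default `"label"`.
#' @param config An [mfo_config()]; defaults to 20 moths, 50 iterations.
#' @param spec A [fitness_spec()].
#' @return An object of class `mfo_selection` with fields `mask` (named
#'   logical), `selected` (feature names), `fitness`, `cv_error`,
#'   `n_selected`, `trace`, and `config_echo`.
#' @export
select_features <- function(data, label_col = "label",
                            config = mfo_config(n_moths = 20,
                                                max_iterations = 50),
                            spec = fitness_spec()) {
  ev <- make_fitness_evaluator(data, label_col, spec)
  if (ev$d < 2) stop("need at least two feature columns", call. = FALSE)
  objective <- function(pos) ev$evaluate(binarize_position(pos))$fitness
  res <- mfo_optimize(objective, mfo_search_space(0, 1, dims = ev$d), config)
  mask <- binarize_position(res$best_position)
  names(mask) <- ev$features
  best <- ev$evaluate(mask)
  structure(list(mask = mask,
                 selected = ev$features[mask],
                 fitness = best$fitness,
                 cv_error = best$cv_error,
                 n_selected = sum(mask),
                 trace = res$trace,
                 config_echo = list(mfo = unclass(config),
                                    fitness = unclass(spec),
                                    label_col = label_col,
                                    d = ev$d)),
            class = "mfo_selection")
}

#' Exhaustive search over all nonempty feature masks (test oracle)
#'
#' Evaluates [selection_fitness()] for every one of the `2^d - 1` nonempty
#' masks and returns the global minimum (lowest-index mask on ties). Refused
#' for `d > 15`.
#'
#' @inheritParams select_features
#' @param spec A [fitness_spec()].
#' @return List with `mask`, `fitness`, `cv_error`, `n_selected`.
#' @export
exhaustive_selection <- function(data, label_col = "label",
                                 spec = fitness_spec()) {
  ev <- make_fitness_evaluator(data, label_col, spec)
  if (ev$d > 15) {
    stop("exhaustive search refused for more than 15 features", call. = FALSE)
  }
  best <- NULL
  for (code in seq_len(2^ev$d - 1)) {
    mask <- as.logical(bitwAnd(bitwShiftR(code, seq_len(ev$d) - 1L), 1L))
    out <- ev$evaluate(mask)
    if (is.null(best) || out$fitness < best$fitness) {
      best <- list(mask = stats::setNames(mask, ev$features),
                   fitness = out$fitness, cv_error = out$cv_error,
                   n_selected = sum(mask))
    }
  }
  best
}

#' @export
print.mfo_selection <- function(x, ...) {
  cat(sprintf("<mfo_selection> %d of %d features selected\n",
              x$n_selected, x$config_echo$d))
  cat(sprintf("  fitness %.4f  (cv error %.4f)\n", x$fitness, x$cv_error))
  invisible(x)
}

#' Tidy a feature selection
#'
#' @param x An `mfo_selection`.
#' @param ... Unused.
#' @return Tibble with one row per feature and its selection status.
#' @method tidy mfo_selection
#' @export
tidy.mfo_selection <- function(x, ...) {
  tibble::tibble(feature = names(x$mask), selected = unname(x$mask))
}

#' One-row summary of a feature selection
#'
#' @param x An `mfo_selection`.
#' @param ... Unused.
#' @method glance mfo_selection
#' @export
glance.mfo_selection <- function(x, ...) {
  tibble::tibble(n_selected = x$n_selected,
                 n_features = x$config_echo$d,
                 fitness = x$fitness,
                 cv_error = x$cv_error,
                 iterations = length(x$trace),
                 seed = x$config_echo$mfo$seed)
}

#' Convergence plot for a feature selection run
#'
#' @param object An `mfo_selection`.
#' @param ... Unused.
#' @method autoplot mfo_selection
#' @export
autoplot.mfo_selection <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$trace),
                       best_fitness = object$trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration,
                                   y = .data$best_fitness)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Iteration", y = "Best wrapper fitness",
                  title = "Feature-selection convergence") +
    ggplot2::theme_minimal()
}

#' Serialize / restore a selection result as JSON
#'
#' The mask is stored as selected column indices together with the full
#' configuration echo, enough to audit or re-run the selection.
#'
#' @param x An `mfo_selection`.
#' @param path Output path.
#' @export
write_selection_json <- function(x, path) {
  jsonlite::write_json(
    list(selected_indices = which(unname(x$mask)),
         selected_names = x$selected,
         n_features = x$config_echo$d,
         fitness = x$fitness,
         cv_error = x$cv_error,
         trace = x$trace,
         config = x$config_echo),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
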