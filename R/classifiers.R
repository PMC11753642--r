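# Classifier preset registry.
#
# Ten presets mirroring the preset families common in point-and-click ML
# toolboxes: three SVM kernels, linear discriminant and a subspace
# discriminant ensemble, kernel naive Bayes, and four KNN variants. The
# literature this package serves expands some of these abbreviations
# inconsistently (e.g. Q-SVM as "Quantum" vs quadratic-kernel SVM, F-KNN as
# "Fuzzy" vs "Fine KNN", KNB as "k-Nearest Neighbor Bayes" vs "Kernel Naive
# Bayes"); the registry implements the widely used preset semantics:
#
#   c_svm   cubic-kernel SVM (polynomial degree 3, coef0 = 1, cost = 1)
#   q_svm   quadratic-kernel SVM (polynomial degree 2, coef0 = 1, cost = 1)
#   mg_svm  medium-width Gaussian SVM (radial, gamma = 1/d, cost = 1)
#   lda     linear discriminant analysis
#   sda     subspace discriminant ensemble (30 LDA learners, dim ceiling(d/2))
#   knb     kernel naive Bayes (per-class per-feature kernel densities)
#   f_knn   fine KNN (k = 1, Euclidean)
#   w_knn   weighted KNN (k = 10, squared-inverse-distance vote, Euclidean)
#   co_knn  cosine KNN (k = 10, cosine distance)
#   c_knn   cubic KNN (k = 10, Minkowski p = 3)
#
# Every hyperparameter above is overridable through `classifier_spec()`.

.preset_ids <- c("c_svm", "w_knn", "q_svm", "lda", "f_knn", "knb",
                 "mg_svm", "sda", "co_knn", "c_knn")

.preset_defaults <- list(
  c_svm  = list(kernel = "polynomial", degree = 3, coef0 = 1, cost = 1),
  q_svm  = list(kernel = "polynomial", degree = 2, coef0 = 1, cost = 1),
  mg_svm = list(kernel = "radial", cost = 1),
  lda    = list(),
  sda    = list(n_learners = 30, subspace_dim = NULL),
  knb    = list(),
  f_knn  = list(k = 1, metric = "euclidean", weighted = FALSE),
  w_knn  = list(k = 10, metric = "euclidean", weighted = TRUE),
  co_knn = list(k = 10, metric = "cosine", weighted = FALSE),
  c_knn  = list(k = 10, metric = "minkowski", p = 3, weighted = FALSE)
)

#' List the classifier presets
#'
#' @return Tibble with preset id, family, and default hyperparameters.
#' @export
list_presets <- function() {
  tibble::tibble(
    preset = .preset_ids,
    family = c("svm", "knn", "svm", "discriminant", "knn", "naive_bayes",
               "svm", "discriminant", "knn", "knn"),
    defaults = purrr::map_chr(.preset_ids, function(p) {
      d <- .preset_defaults[[p]]
      if (length(d) == 0) return("")
      paste(names(d), vapply(d, function(v) paste(format(v), collapse = ","),
                             character(1)), sep = "=", collapse = ", ")
    })
  )
}

normalize_preset <- function(preset) {
  p <- gsub("-", "_", tolower(trimws(preset)))
  if (!p %in% .preset_ids) {
    stop(sprintf("unknown classifier preset '%s'; see list_presets()", preset),
         call. = FALSE)
  }
  p
}

#' Build a classifier specification
#'
#' @param preset One of the registry ids (case-insensitive, `-` or `_`):
#'   C-SVM, W-KNN, Q-SVM, LDA, F-KNN, KNB, MG-SVM, SDA, Co-KNN, C-KNN.
#' @param ... Hyperparameter overrides (see the registry documentation).
#' @param seed Integer seed used by stochastic presets (the subspace
#'   ensemble draws feature subsets).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(preset, ..., seed = 1L) {
  p <- normalize_preset(preset)
  hp <- utils::modifyList(.preset_defaults[[p]], list(...))
  structure(list(preset = p, hyperparams = hp, seed = as.integer(seed)),
            class = "classifier_spec")
}

# ---- fitting ---------------------------------------------------------------

#' Fit a preset classifier
#'
#' @param spec A [classifier_spec()] (or a preset id string).
#' @param x Numeric matrix of training features (rows = samples).
#' @param y Factor of training labels.
#' @return A fitted model of class `mothflame_model`.
#' @export
fit_classifier <- function(spec, x, y) {
  if (is.character(spec)) spec <- classifier_spec(spec)
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nrow(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  hp <- spec$hyperparams
  fit <- switch(
    spec$preset,
    c_svm = , q_svm = , mg_svm = fit_svm(spec$preset, hp, x, y),
    lda = fit_lda(x, y),
    sda = fit_sda(hp, x, y, spec$seed),
    knb = fit_knb(x, y),
    f_knn = , w_knn = , co_knn = , c_knn = fit_knn(hp, x, y)
  )
  structure(list(preset = spec$preset, fit = fit, levels = levels(y)),
            class = "mothflame_model")
}

#' Predict labels from a fitted preset classifier
#'
#' @param model A `mothflame_model` from [fit_classifier()].
#' @param x Numeric matrix of test features.
#' @return Factor of predicted labels with the training levels.
#' @export
predict_classifier <- function(model, x) {
  x <- as.matrix(x)
  pred <- switch(
    model$preset,
    c_svm = , q_svm = , mg_svm = predict_svm(model$fit, x),
    lda = predict_lda(model$fit, x),
    sda = predict_sda(model$fit, x),
    knb = predict_knb(model$fit, x),
    f_knn = , w_knn = , co_knn = , c_knn = predict_knn(model$fit, x)
  )
  factor(as.character(pred), levels = model$levels)
}

# --- SVM (e1071) ---
fit_svm <- function(preset, hp, x, y) {
  gamma <- hp$gamma %||% 1 / ncol(x)
  args <- list(x = x, y = y, kernel = hp$kernel, cost = hp$cost,
               gamma = gamma, scale = apply(x, 2, stats::sd) > 0)
  if (hp$kernel == "polynomial") {
    args$degree <- hp$degree
    args$coef0 <- hp$coef0
  }
  do.call(e1071::svm, args)
}
predict_svm <- function(fit, x) stats::predict(fit, x)

# --- LDA (MASS); constant columns dropped before fitting ---
fit_lda <- function(x, y) {
  keep <- which(apply(x, 2, stats::sd) > 0)
  if (length(keep) == 0) stop("all features are constant", call. = FALSE)
  list(lda = MASS::lda(x[, keep, drop = FALSE], grouping = y), keep = keep)
}
predict_lda <- function(fit, x) {
  stats::predict(fit$lda, x[, fit$keep, drop = FALSE])$class
}

# --- Subspace discriminant ensemble: LDA learners on random feature
# subsets, combined by averaging posteriors (MATLAB-style "Subspace
# Discriminant") ---
fit_sda <- function(hp, x, y, seed) {
  d <- ncol(x)
  m <- hp$subspace_dim %||% max(1L, ceiling(d / 2))
  m <- min(m, d)
  withr::with_seed(seed, {
    learners <- purrr::map(seq_len(hp$n_learners), function(i) {
      idx <- sort(sample.int(d, m))
      sub <- x[, idx, drop = FALSE]
      keep <- which(apply(sub, 2, stats::sd) > 0)
      if (length(keep) == 0) return(NULL)
      fit <- tryCatch(MASS::lda(sub[, keep, drop = FALSE], grouping = y),
                      error = function(e) NULL)
      if (is.null(fit)) NULL else list(idx = idx[keep], lda = fit)
    })
  })
  learners <- purrr::compact(learners)
  if (length(learners) == 0) stop("no subspace learner could be fit", call. = FALSE)
  list(learners = learners, levels = levels(y))
}
predict_sda <- function(fit, x) {
  post <- matrix(0, nrow(x), length(fit$levels),
                 dimnames = list(NULL, fit$levels))
  for (ln in fit$learners) {
    p <- stats::predict(ln$lda, x[, ln$idx, drop = FALSE])$posterior
    post[, colnames(p)] <- post[, colnames(p)] + p
  }
  factor(fit$levels[max.col(post, ties.method = "first")], levels = fit$levels)
}

# --- Kernel naive Bayes: per-class, per-feature Gaussian-kernel density
# estimates; near-constant features fall back to a narrow Gaussian ---
fit_knb <- function(x, y) {
  classes <- levels(y)
  dens <- purrr::map(classes, function(cl) {
    xi <- x[y == cl, , drop = FALSE]
    purrr::map(seq_len(ncol(x)), function(j) {
      v <- xi[, j]
      if (stats::sd(v) < 1e-10 || length(v) < 2) {
        list(type = "gauss", mean = mean(v),
             sd = max(stats::sd(x[, j]), 1e-6))
      } else {
        d <- stats::density(v, n = 512, cut = 3)
        list(type = "kde", x = d$x, y = pmax(d$y, 1e-12))
      }
    })
  })
  names(dens) <- classes
  list(densities = dens, priors = table(y) / length(y), levels = classes)
}
predict_knb <- function(fit, x) {
  ll <- sapply(fit$levels, function(cl) {
    lj <- vapply(seq_len(ncol(x)), function(j) {
      dj <- fit$densities[[cl]][[j]]
      if (dj$type == "kde") {
        v <- stats::approx(dj$x, dj$y, xout = x[, j], rule = 2)$y
        log(pmax(v, 1e-12))
      } else {
        stats::dnorm(x[, j], dj$mean, dj$sd, log = TRUE)
      }
    }, numeric(nrow(x)))
    if (nrow(x) == 1) lj <- matrix(lj, nrow = 1)
    rowSums(lj) + log(as.numeric(fit$priors[cl]))
  })
  if (nrow(x) == 1) ll <- matrix(ll, nrow = 1, dimnames = list(NULL, fit$levels))
  factor(fit$levels[max.col(ll, ties.method = "first")], levels = fit$levels)
}

# --- KNN variants. Features are standardized with training statistics.
# Weighted voting uses squared inverse distance; ties go to the first
# class level. ---
fit_knn <- function(hp, x, y) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  list(x = scale(x, ctr, scl), y = y, ctr = ctr, scl = scl,
       k = hp$k, metric = hp$metric, p = hp$p %||% 2,
       weighted = isTRUE(hp$weighted), levels = levels(y))
}
predict_knn <- function(fit, x) {
  xs <- scale(as.matrix(x), fit$ctr, fit$scl)
  d <- knn_distances(xs, fit$x, fit$metric, fit$p)
  k <- min(fit$k, nrow(fit$x))
  pred <- apply(d, 1, function(di) {
    nn <- order(di)[seq_len(k)]
    w <- if (fit$weighted) 1 / pmax(di[nn], 1e-12)^2 else rep(1, k)
    votes <- tapply(w, factor(fit$y[nn], levels = fit$levels), sum,
                    default = 0)
    fit$levels[which.max(votes)]
  })
  factor(pred, levels = fit$levels)
}
knn_distances <- function(a, b, metric, p = 2) {
  if (metric == "euclidean") {
    d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
    sqrt(pmax(d2, 0))
  } else if (metric == "cosine") {
    na <- sqrt(pmax(rowSums(a^2), 1e-12))
    nb <- sqrt(pmax(rowSums(b^2), 1e-12))
    1 - tcrossprod(a / na, b / nb)
  } else if (metric == "minkowski") {
    t(apply(a, 1, function(r) colSums(abs(t(b) - r)^p)^(1 / p)))
  } else {
    stop("unknown metric: ", metric, call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
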