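# Seeded synthetic-data generators with known ground truth.
#
# Two generators stand in for the data a real deployment would supply:
# (1) multiclass Gaussian feature matrices with a planted informative
# subset among pure-noise columns, emulating the role of deep feature
# tables; (2) toy "lesion-on-leaf" images — a colored lesion of a
# class-specific shape on a uniform background with pixel noise — so the
# image stages (augmentation, extraction) run without any real dataset.

#' Gaussian feature matrix with a planted informative subset
#'
#' Informative columns are drawn `Normal(mu_k, 1)` where the class means
#' `mu_k` sit at the vertices of a regular simplex scaled so every pair of
#' class means is exactly `separation` within-class standard deviations
#' apart; noise columns are `Normal(0, 1)` independent of class. Column
#' order is randomly permuted (seeded) so informative features are not
#' trivially positional; their true indices are returned.
#'
#' @param n_per_class Samples per class; default 60.
#' @param k_classes Number of classes (>= 2); default 3.
#' @param d_informative Informative feature count; must be >= `k_classes`
#'   so the simplex construction is exact; default 5.
#' @param d_noise Noise feature count; default 45.
#' @param separation Class-mean distance in units of within-class sigma;
#'   default 2.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return List with `features` (tibble of `d_informative + d_noise`
#'   numeric columns plus `label`) and `informative` (integer positions of
#'   the informative columns in the tibble).
#' @export
synthetic_features <- function(n_per_class = 60, k_classes = 3,
                               d_informative = 5, d_noise = 45,
                               separation = 2, seed = 1L) {
  stopifnot(n_per_class >= 2, k_classes >= 2, d_informative >= 1,
            d_noise >= 0, separation >= 0)
  if (d_informative < k_classes) {
    stop("d_informative must be at least k_classes for the simplex means",
         call. = FALSE)
  }
  d <- d_informative + d_noise
  n <- n_per_class * k_classes
  withr::with_seed(seed, {
    # simplex vertices: scaled unit vectors give equal pairwise distances
    mu <- matrix(0, k_classes, d_informative)
    for (k in seq_len(k_classes)) mu[k, k] <- separation / sqrt(2)
    y <- rep(seq_len(k_classes), each = n_per_class)
    x <- matrix(stats::rnorm(n * d), n, d)
    x[, seq_len(d_informative)] <- x[, seq_len(d_informative)] + mu[y, ]
    perm <- sample.int(d)
    x <- x[, perm, drop = FALSE]
    informative <- match(seq_len(d_informative), perm)
    colnames(x) <- sprintf("feat_%03d", seq_len(d))
    features <- tibble::as_tibble(as.data.frame(x))
    features$label <- sprintf("class_%d", y)
    list(features = features, informative = sort(informative))
  })
}

#' Toy lesion-on-leaf images
#'
#' Each image is a uniform background with one lesion — a class-specific
#' (shape, color) signature among disc, ring and streak — placed at a
#' seeded random position, plus Gaussian pixel noise clipped to
#' `[0, 255]`. Labels are correct by construction.
#'
#' @param k_classes Number of classes; default 4.
#' @param images_per_class Images per class; default 40.
#' @param height,width Canvas size in pixels; default 64 x 64.
#' @param shapes Character vector (recycled over classes) from
#'   `"disc"`, `"ring"`, `"streak"`.
#' @param colors List of RGB triplets (0-255), one per class; defaults to a
#'   palette of well-separated lesion colors.
#' @param background RGB triplet of the leaf background; default a mid
#'   green.
#' @param noise_sd Gaussian pixel-noise standard deviation; default 8.
#' @param lesion_radius Lesion radius in pixels; defaults to a sixth of the
#'   shorter canvas side. A lesion that cannot fit on the canvas is an
#'   error.
#' @param seed Integer seed.
#' @return List of [labeled_image()] objects, `k_classes *
#'   images_per_class` long.
#' @export
synthetic_images <- function(k_classes = 4, images_per_class = 40,
                             height = 64, width = 64,
                             shapes = c("disc", "ring", "streak"),
                             colors = NULL,
                             background = c(60, 150, 60),
                             noise_sd = 8, lesion_radius = NULL,
                             seed = 1L) {
  stopifnot(k_classes >= 2, images_per_class >= 1, height >= 8, width >= 8,
            noise_sd >= 0)
  palette <- colors %||% list(c(139, 69, 19), c(225, 205, 60),
                              c(130, 30, 30), c(235, 140, 40),
                              c(100, 40, 130), c(210, 210, 210))
  if (length(palette) < k_classes) {
    stop("supply one lesion color per class", call. = FALSE)
  }
  shapes <- rep_len(shapes, k_classes)
  sig <- paste(shapes, purrr::map_chr(palette[seq_len(k_classes)],
                                      paste, collapse = ","))
  if (anyDuplicated(sig)) {
    stop("each class needs a distinct (shape, color) signature",
         call. = FALSE)
  }
  r <- lesion_radius %||% floor(min(height, width) / 6)
  if (2 * r + 2 > min(height, width)) {
    stop("lesion does not fit on the canvas", call. = FALSE)
  }
  withr::with_seed(seed, {
    out <- vector("list", k_classes * images_per_class)
    i <- 0L
    for (k in seq_len(k_classes)) {
      col <- palette[[k]]
      for (j in seq_len(images_per_class)) {
        i <- i + 1L
        px <- array(rep(background, each = height * width),
                    c(height, width, 3))
        cy <- sample((r + 2):(height - r - 1), 1)
        cx <- sample((r + 2):(width - r - 1), 1)
        rows <- matrix(seq_len(height), height, width)
        cols <- matrix(seq_len(width), height, width, byrow = TRUE)
        dist2 <- (rows - cy)^2 + (cols - cx)^2
        mask <- switch(shapes[k],
          disc = dist2 <= r^2,
          ring = dist2 <= r^2 & dist2 >= (0.55 * r)^2,
          streak = abs(rows - cy) <= max(1, floor(r / 3)) &
                   abs(cols - cx) <= 2 * r,
          stop("unknown lesion shape: ", shapes[k], call. = FALSE))
        for (ch in 1:3) {
          plane <- px[, , ch]
          plane[mask] <- col[ch]
          px[, , ch] <- plane
        }
        if (noise_sd > 0) {
          px <- px + array(stats::rnorm(length(px), 0, noise_sd), dim(px))
        }
        px <- pmin(pmax(px, 0), 255)
        out[[i]] <- labeled_image(px, sprintf("class_%d", k),
                                  sprintf("synthetic_%02d_%03d", k, j))
      }
    }
    out
  })
}
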