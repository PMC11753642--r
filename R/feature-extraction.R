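# Deterministic block-statistics feature extraction.
#
# The pipeline treats feature extraction as a pluggable contract: anything
# that maps an image to a fixed-length numeric vector (e.g. the penultimate
# layer of a pretrained CNN, supplied externally as a delimited feature
# table) can feed selection, fusion and classification. The built-in
# extractor is a simple deterministic one — per-block, per-channel mean and
# standard deviation on a g x g grid — so the full pipeline is exercisable
# with no trained network.

#' Block-statistics feature extractor
#'
#' Partitions an RGB image into a `grid x grid` lattice of equal blocks
#' (edge blocks absorb any remainder rows/columns) and emits the mean and
#' standard deviation of each block in each channel, giving a vector of
#' length `2 * 3 * grid^2` with values in `[0, 255]`.
#'
#' @param img A [labeled_image()] or an H x W x 3 array.
#' @param grid Blocks per side; default 4 (96 features).
#' @return Named numeric feature vector.
#' @export
toy_extract <- function(img, grid = 4L) {
  px <- if (inherits(img, "labeled_image")) img$pixels else img
  d <- dim(px)
  if (length(d) != 3 || d[3] != 3) {
    stop("toy_extract requires a 3-channel (RGB) image", call. = FALSE)
  }
  g <- as.integer(grid)
  stopifnot(g >= 1, d[1] >= g, d[2] >= g)
  # block boundaries: equal floor-sized blocks, remainder into the last
  row_edges <- c(seq(0, (g - 1) * (d[1] %/% g), by = d[1] %/% g), d[1])
  col_edges <- c(seq(0, (g - 1) * (d[2] %/% g), by = d[2] %/% g), d[2])
  feats <- numeric(2 * 3 * g * g)
  nms <- character(2 * 3 * g * g)
  idx <- 1L
  for (ch in 1:3) {
    for (bi in seq_len(g)) {
      for (bj in seq_len(g)) {
        block <- px[(row_edges[bi] + 1):row_edges[bi + 1],
                    (col_edges[bj] + 1):col_edges[bj + 1], ch]
        v <- as.numeric(block)
        feats[idx] <- mean(v)
        feats[idx + 1L] <- if (length(v) > 1) stats::sd(v) else 0
        nms[idx] <- sprintf("c%d_b%d_%d_mean", ch, bi, bj)
        nms[idx + 1L] <- sprintf("c%d_b%d_%d_sd", ch, bi, bj)
        idx <- idx + 2L
      }
    }
  }
  stats::setNames(feats, nms)
}

#' Extract a feature table from a list of images
#'
#' Applies an extractor to every image and assembles the rows into a
#' feature table (tibble with a `label` column), preserving input order.
#' Images for which the extractor fails are dropped with a warning; the
#' number dropped is attached as attribute `"n_dropped"`.
#'
#' @param images List of [labeled_image()] objects.
#' @param grid Grid size for the built-in extractor (ignored when
#'   `extractor` is supplied).
#' @param extractor Optional function `image -> named numeric vector`
#'   replacing the built-in block-statistics extractor.
#' @return Tibble of features plus a `label` column.
#' @export
extract_features <- function(images, grid = 4L, extractor = NULL) {
  fn <- extractor %||% function(im) toy_extract(im, grid = grid)
  rows <- purrr::map(images, function(im) {
    tryCatch(list(f = fn(im), label = im$label), error = function(e) NULL)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0) {
    warning(sprintf("%d image(s) dropped during extraction", dropped),
            call. = FALSE)
  }
  rows <- purrr::compact(rows)
  if (length(rows) == 0) stop("no image could be extracted", call. = FALSE)
  mat <- do.call(rbind, purrr::map(rows, "f"))
  out <- tibble::as_tibble(as.data.frame(mat))
  out$label <- purrr::map_chr(rows, "label")
  attr(out, "n_dropped") <- dropped
  out
}
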