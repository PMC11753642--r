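# Label-preserving image augmentation: 90-degree rotation and both flips.
#
# Images are H x W x C arrays of 8-bit intensities (0..255), C = 1 or 3,
# wrapped with their class label and an origin tag. All three transforms
# are deterministic bijections of the pixel grid: the flips are
# involutions and the rotation has order four.

#' Construct a labeled image
#'
#' @param pixels Numeric H x W matrix or H x W x C array (C = 1 or 3) of
#'   intensities in `[0, 255]`.
#' @param label Class label.
#' @param origin Provenance tag (e.g. source filename); augmentation ops
#'   append their own tag.
#' @return An object of class `labeled_image`.
#' @export
labeled_image <- function(pixels, label, origin = NA_character_) {
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  d <- dim(pixels)
  if (length(d) != 3 || !(d[3] %in% c(1L, 3L)) || d[1] < 1 || d[2] < 1) {
    stop("pixels must be an HxW matrix or HxWxC array with C = 1 or 3",
         call. = FALSE)
  }
  structure(list(pixels = pixels, label = as.character(label),
                 origin = as.character(origin)),
            class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<labeled_image> %dx%dx%d  label: %s  origin: %s\n",
              d[1], d[2], d[3], x$label, x$origin))
  invisible(x)
}

apply_pixels <- function(img, fn, tag) {
  if (inherits(img, "labeled_image")) {
    px <- fn(img$pixels)
    labeled_image(px, img$label,
                  if (is.na(img$origin)) tag else paste(img$origin, tag,
                                                        sep = "|"))
  } else {
    was_matrix <- is.matrix(img)
    arr <- if (was_matrix) array(img, c(dim(img), 1L)) else img
    out <- fn(arr)
    if (was_matrix) out[, , 1] else out
  }
}

rot90_channel <- function(m) t(m)[ncol(m):1, , drop = FALSE]

#' Rotate an image 90 degrees counter-clockwise
#'
#' An H x W image becomes W x H; the label is unchanged. Applying the
#' rotation four times recovers the original image.
#'
#' @param img A [labeled_image()], or a raw matrix/array.
#' @return The rotated image of the same type.
#' @examples
#' img_rot90(matrix(1:4, 2, byrow = TRUE)) # [[2,4],[1,3]]
#' @export
img_rot90 <- function(img) {
  apply_pixels(img, function(a) {
    d <- dim(a)
    out <- array(0, c(d[2], d[1], d[3]))
    for (c in seq_len(d[3])) out[, , c] <- rot90_channel(a[, , c])
    out
  }, "rot90")
}

#' Flip an image vertically (upside-down) or horizontally (left-right)
#'
#' `img_flip_ud()` reverses the row order; `img_flip_lr()` reverses the
#' column order. Both are involutions and preserve the label.
#'
#' @param img A [labeled_image()], or a raw matrix/array.
#' @return The flipped image of the same type.
#' @export
img_flip_ud <- function(img) {
  apply_pixels(img, function(a) a[dim(a)[1]:1, , , drop = FALSE], "flip_ud")
}

#' @rdname img_flip_ud
#' @export
img_flip_lr <- function(img) {
  apply_pixels(img, function(a) a[, dim(a)[2]:1, , drop = FALSE], "flip_lr")
}

#' Expand a dataset with the three augmentation transforms
#'
#' For every input image and every repeat, emits the original plus its
#' 90-degree rotation, vertical flip and horizontal flip — four outputs per
#' image per repeat, so per-class counts scale uniformly by `4 * repeats`.
#' With `compose = TRUE` the transforms are additionally applied to the
#' already-augmented images of the previous pass, which reaches larger
#' target counts.
#'
#' @param images List of [labeled_image()] objects.
#' @param repeats Integer >= 1; default 1.
#' @param compose If `TRUE`, each repeat augments the previous repeat's
#'   output instead of the originals (counts grow as 4^repeats per image).
#' @return List of `labeled_image` objects; the manifest (tibble of label,
#'   origin, op) is attached as attribute `"manifest"` and available via
#'   [augmentation_manifest()].
#' @export
augment_images <- function(images, repeats = 1L, compose = FALSE) {
  stopifnot(repeats >= 1)
  expand_once <- function(imgs) {
    purrr::flatten(purrr::map(imgs, function(im) {
      orig <- if (inherits(im, "labeled_image")) im else
        labeled_image(im, label = NA_character_)
      list(orig, img_rot90(orig), img_flip_ud(orig), img_flip_lr(orig))
    }))
  }
  if (length(images) == 0) {
    out <- list()
  } else if (compose) {
    out <- images
    for (r in seq_len(repeats)) out <- expand_once(out)
  } else {
    out <- purrr::flatten(purrr::map(seq_len(repeats),
                                     function(r) expand_once(images)))
  }
  manifest <- purrr::map_dfr(seq_along(out), function(i) {
    tibble::tibble(index = i, label = out[[i]]$label,
                   origin = out[[i]]$origin)
  })
  attr(out, "manifest") <- manifest
  out
}

#' Manifest of an augmented dataset
#'
#' @param images Result of [augment_images()] (or [read_image_dir()]).
#' @return Tibble with one row per image: index, label, origin.
#' @export
augmentation_manifest <- function(images) {
  m <- attr(images, "manifest")
  if (is.null(m)) {
    m <- purrr::map_dfr(seq_along(images), function(i) {
      tibble::tibble(index = i, label = images[[i]]$label,
                     origin = images[[i]]$origin)
    })
  }
  m
}

# ---- directory I/O (class-per-folder PNG trees) ---------------------------

#' Read a class-per-folder directory of PNG images
#'
#' Each subdirectory of `path` is a class; every `.png` file inside becomes
#' a [labeled_image()] with the subdirectory name as label. Unreadable
#' files are skipped with a warning and counted in the attached manifest
#' attribute `"n_skipped"`.
#'
#' @param path Directory with one subdirectory per class.
#' @return List of `labeled_image` objects.
#' @export
read_image_dir <- function(path) {
  if (!dir.exists(path)) stop("directory not found: ", path, call. = FALSE)
  classes <- list.dirs(path, recursive = FALSE, full.names = FALSE)
  skipped <- 0L
  out <- list()
  for (cl in classes) {
    files <- list.files(file.path(path, cl), pattern = "\\.png$",
                        full.names = TRUE, ignore.case = TRUE)
    for (f in files) {
      px <- tryCatch(png::readPNG(f), error = function(e) NULL)
      if (is.null(px)) {
        warning("skipping unreadable image: ", f, call. = FALSE)
        skipped <- skipped + 1L
        next
      }
      if (length(dim(px)) == 3 && dim(px)[3] == 4) px <- px[, , 1:3]
      out[[length(out) + 1L]] <- labeled_image(round(px * 255), cl,
                                               basename(f))
    }
  }
  attr(out, "n_skipped") <- skipped
  out
}

#' Write labeled images to a class-per-folder PNG tree
#'
#' Mirrors the class layout under `path`, suffixes filenames with the
#' applied-op tag, and writes a `manifest.csv` (filename, class, origin).
#'
#' @param images List of [labeled_image()] objects.
#' @param path Output directory (created if missing).
#' @return The manifest tibble, invisibly.
#' @export
write_image_dir <- function(images, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::map_dfr(seq_along(images), function(i) {
    im <- images[[i]]
    cls_dir <- file.path(path, im$label)
    dir.create(cls_dir, showWarnings = FALSE)
    tag <- if (is.na(im$origin)) "img" else gsub("[^A-Za-z0-9_.|-]", "_",
                                                 im$origin)
    tag <- gsub("\\|", "_", tag)
    fname <- sprintf("%04d_%s.png", i, tag)
    px <- im$pixels / 255
    png::writePNG(if (dim(px)[3] == 1) px[, , 1] else px,
                  file.path(cls_dir, fname))
    tibble::tibble(filename = file.path(im$label, fname), class = im$label,
                   origin = im$origin)
  })
  utils::write.csv(rows, file.path(path, "manifest.csv"), row.names = FALSE)
  invisible(rows)
}
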