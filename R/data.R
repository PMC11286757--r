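# Dataset container, image I/O, resizing and the stratified split.

#' Labeled image set
#'
#' The unit the pipeline trains and evaluates on: a list of (H, W, 3)
#' images in \[0, 1\] with a class label per image, optional train/val/test
#' split tags and provenance (original vs augmented) markers.
#'
#' @param images list of (H, W, C) arrays with values in \[0, 1\].
#' @param labels factor (or character) of class labels, one per image.
#' @param split optional character/factor of `"train"`, `"val"`, `"test"`
#'   tags, one per image.
#' @param provenance optional `"original"` / `"augmented"` markers.
#' @param geometry optional per-image list of ground-truth geometry (the
#'   synthetic generator stores the cell bounding box here).
#' @return An object of class `cell_image_set`.
#' @export
labeled_image_set <- function(images, labels, split = NULL,
                              provenance = NULL, geometry = NULL) {
  if (!is.factor(labels)) labels <- factor(labels)
  if (length(images) != length(labels))
    stop("images and labels must have the same length")
  if (!is.null(split)) {
    split <- factor(as.character(split), levels = c("train", "val", "test"))
    if (length(split) != length(images))
      stop("split must tag every image")
  }
  if (is.null(provenance)) provenance <- rep("original", length(images))
  structure(list(images = images, labels = labels, split = split,
                 provenance = provenance, geometry = geometry),
            class = "cell_image_set")
}

#' @export
print.cell_image_set <- function(x, ...) {
  cat(sprintf("cell_image_set: %d images, %d classes\n",
              length(x$images), nlevels(x$labels)))
  print(table(label = x$labels,
              split = if (is.null(x$split)) rep("(none)", length(x$images))
              else x$split))
  invisible(x)
}

#' @export
length.cell_image_set <- function(x) length(x$images)

subset_image_set <- function(data, idx) {
  labeled_image_set(
    images = data$images[idx],
    labels = factor(as.character(data$labels)[idx],
                    levels = levels(data$labels)),
    split = if (is.null(data$split)) NULL else as.character(data$split)[idx],
    provenance = data$provenance[idx],
    geometry = if (is.null(data$geometry)) NULL else data$geometry[idx])
}

#' Bilinear image resize
#'
#' @param img an (H, W) matrix or (H, W, C) array.
#' @param height,width target size.
#' @return Resized image of the same rank.
#' @export
resize_bilinear <- function(img, height, width) {
  d <- dim(img)
  flat <- length(d) == 2L
  if (flat) dim(img) <- c(d, 1L)
  y <- drop_batch(.bilinear_fwd(as_batch(img), as.integer(height),
                                as.integer(width)))
  if (flat) dim(y) <- c(height, width)
  y
}

read_one_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png" && requireNamespace("png", quietly = TRUE)) {
    png::readPNG(path)
  } else if (requireNamespace("EBImage", quietly = TRUE)) {
    a <- EBImage::imageData(EBImage::readImage(path))
    # EBImage stores (x = width, y = height[, channel])
    if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
  } else {
    stop("reading '", path, "' requires the png or EBImage package")
  }
  d <- dim(img)
  if (is.null(d) || length(d) == 2L) {
    img <- array(rep(as.numeric(img), 3L), dim = c(dim(img), 3L))
  } else if (d[3L] == 1L) {
    img <- array(rep(img, 3L), dim = c(d[1:2], 3L))
  } else if (d[3L] > 3L) {
    img <- img[, , 1:3, drop = FALSE]   # drop alpha
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

#' Load a directory-per-class image tree
#'
#' Reads JPEG/PNG files from one subdirectory per class, converts grayscale
#' to 3 channels, rescales values to \[0, 1\] and resizes every image to
#' `size x size x 3` (plain bilinear resize; the aspect ratio is not
#' preserved). Undecodable files are skipped with a warning; an empty class
#' is an error. Per-class counts are reported via `message()`.
#'
#' @param root_dir directory containing one subdirectory per class.
#' @param class_subdirs named character vector mapping subdirectory name to
#'   class label; defaults to the four leukocyte classes.
#' @param size output image side length (default 224).
#' @return A [labeled_image_set()].
#' @export
load_image_dataset <- function(root_dir,
                               class_subdirs = setNames(CELL_CLASSES,
                                                        CELL_CLASSES),
                               size = 224L) {
  images <- list(); labels <- character()
  for (sub in names(class_subdirs)) {
    cls <- class_subdirs[[sub]]
    dirp <- file.path(root_dir, sub)
    files <- sort(list.files(dirp, pattern = "\\.(jpe?g|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    n_ok <- 0L; n_bad <- 0L
    for (f in files) {
      img <- tryCatch(read_one_image(f), error = function(e) NULL)
      if (is.null(img)) { n_bad <- n_bad + 1L; next }
      if (dim(img)[1L] != size || dim(img)[2L] != size)
        img <- resize_bilinear(img, size, size)
      images[[length(images) + 1L]] <- img
      labels <- c(labels, cls)
      n_ok <- n_ok + 1L
    }
    if (n_bad > 0L)
      warning(sprintf("class '%s': skipped %d undecodable file(s)", cls,
                      n_bad))
    if (n_ok == 0L) stop(sprintf("class '%s' has no decodable images", cls))
    message(sprintf("loaded %d images for class '%s'", n_ok, cls))
  }
  labeled_image_set(images, factor(labels, levels = sort(unique(labels))))
}

#' Write an image set as a directory-per-class tree
#'
#' PNG files plus a `manifest.csv` (path, label, split, provenance), the
#' same layout [load_image_dataset()] consumes.
#'
#' @param data a [labeled_image_set()].
#' @param out_dir output directory (created if missing).
#' @return The manifest data frame, invisibly.
#' @export
write_image_dataset <- function(data, out_dir) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("writing images requires the png package")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", length(data$images))
  for (i in seq_along(data$images)) {
    cls <- as.character(data$labels[i])
    dir.create(file.path(out_dir, cls), showWarnings = FALSE)
    rel <- file.path(cls, sprintf("%s_%04d.png", cls, i))
    png::writePNG(data$images[[i]], file.path(out_dir, rel))
    rows[[i]] <- data.frame(
      path = rel, label = cls,
      split = if (is.null(data$split)) NA_character_ else
        as.character(data$split[i]),
      provenance = data$provenance[i])
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Stratified train/test split
#'
#' Assigns `round(train_frac * n_c)` images of every class to the training
#' split and the remainder to the test split (disjoint by construction),
#' optionally carving a validation fraction out of the training portion.
#' Deterministic under `seed`.
#'
#' @param data a [labeled_image_set()]; every class needs at least 2 images.
#' @param train_frac training fraction (default 0.8, the 80:20 protocol).
#' @param seed integer seed.
#' @param val_frac fraction of each class (taken from the training portion)
#'   tagged `"val"` (default 0).
#' @return The same set with split tags assigned.
#' @export
split_train_test <- function(data, train_frac = 0.8, seed = 1L,
                             val_frac = 0) {
  stopifnot(train_frac > 0, train_frac < 1, val_frac >= 0,
            val_frac < train_frac)
  counts <- table(data$labels)
  if (any(counts < 2L))
    stop("every class needs at least 2 images to be split")
  set.seed(seed)
  split <- rep("test", length(data$images))
  for (cl in levels(data$labels)) {
    idx <- which(data$labels == cl)
    n_train <- round(train_frac * length(idx))
    n_val <- round(val_frac * length(idx))
    shuffled <- sample(idx)
    train_idx <- shuffled[seq_len(n_train)]
    split[train_idx] <- "train"
    if (n_val > 0L) split[train_idx[seq_len(min(n_val, n_train))]] <- "val"
  }
  data$split <- factor(split, levels = c("train", "val", "test"))
  data
}

# stack images (resized to the model input size) into an (H, W, C, N) batch
images_to_batch <- function(images, input_size) {
  H <- input_size[1L]; W <- input_size[2L]; C <- input_size[3L]
  out <- array(0, dim = c(H, W, C, length(images)))
  for (i in seq_along(images)) {
    img <- images[[i]]
    if (dim(img)[1L] != H || dim(img)[2L] != W)
      img <- resize_bilinear(img, H, W)
    out[, , , i] <- img
  }
  out
}
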