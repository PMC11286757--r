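# Augmentation transforms used both for stain/orientation robustness and to
# balance the per-class image counts. All transforms act on decoded images:
# (H, W, C) arrays with values in [0, 1], 0-based pixel index semantics,
# row-major (row, col).

#' Augmentation settings
#'
#' The standard recipe: horizontal flipping, rotation to 10 degrees,
#' zooming with a scale of 2, and random contrast enhancement (the contrast
#' factor range is left open by the recipe; the default is a
#' mean-anchored stretch drawn from (0.7, 1.3)). A transform is considered
#' disabled when its parameter is neutral (`flip = FALSE`,
#' `rotation_deg = 0`, `zoom_scale = 1`, `contrast_range = c(1, 1)`).
#'
#' @param flip enable horizontal flipping (default `TRUE`).
#' @param rotation_deg rotation magnitude in degrees; synthesized images are
#'   rotated by +/- this angle (default 10).
#' @param zoom_scale magnification factor (> 0, default 2).
#' @param contrast_range multiplicative contrast factor bounds
#'   `(low, high)` with `0 < low <= 1 <= high`.
#' @param seed integer seed making [balance_augment()] deterministic.
#' @return An object of class `augmentation_spec`.
#' @export
augmentation_spec <- function(flip = TRUE, rotation_deg = 10,
                              zoom_scale = 2, contrast_range = c(0.7, 1.3),
                              seed = 1L) {
  stopifnot(is.finite(rotation_deg), zoom_scale > 0,
            length(contrast_range) == 2L,
            contrast_range[1L] > 0, contrast_range[1L] <= 1,
            contrast_range[2L] >= 1)
  structure(list(flip_enabled = isTRUE(flip),
                 rotation_deg = as.numeric(rotation_deg),
                 zoom_scale = as.numeric(zoom_scale),
                 contrast_range = as.numeric(contrast_range),
                 seed = as.integer(seed)),
            class = "augmentation_spec")
}

#' Horizontal flip
#'
#' Mirrors the image about its vertical axis: `out[i, j] = in[i, W-1-j]`
#' (0-based) per channel. Applying it twice recovers the input exactly.
#'
#' @param img an (H, W) matrix or (H, W, C) array.
#' @return Image of the same shape.
#' @export
flip_horizontal <- function(img) {
  d <- dim(img)
  if (is.null(d)) stop("img must be a matrix or array")
  W <- d[2L]
  if (length(d) == 2L) img[, W:1, drop = FALSE] else img[, W:1, , drop = FALSE]
}

# bilinear sample of channel matrix `ch` at fractional 0-based (rows, cols);
# out-of-canvas samples return `fill`
bilinear_sample <- function(ch, rows, cols, fill = 0) {
  H <- nrow(ch); W <- ncol(ch)
  inside <- rows > -1 & rows < H & cols > -1 & cols < W
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  # clamp the 4 taps; taps outside the canvas contribute `fill`
  gv <- function(ri, ci) {
    ok <- ri >= 0 & ri < H & ci >= 0 & ci < W
    v <- rep(fill, length(ri))
    idx <- which(ok)
    v[idx] <- ch[cbind(ri[idx] + 1L, ci[idx] + 1L)]
    v
  }
  v <- (1 - fr) * (1 - fc) * gv(r0, c0) +
    (1 - fr) * fc * gv(r0, c0 + 1) +
    fr * (1 - fc) * gv(r0 + 1, c0) +
    fr * fc * gv(r0 + 1, c0 + 1)
  v[!inside] <- fill
  v
}

#' Rotate an image
#'
#' Rotates the image content clockwise by `theta_deg` degrees with bilinear
#' interpolation; samples falling outside the canvas are filled with 0
#' (black). By default rotation is about the image center; `about =
#' "origin"` rotates about the coordinate origin (the top-left pixel), the
#' literal index-formula reading.
#'
#' @param img an (H, W) matrix or (H, W, C) array.
#' @param theta_deg rotation angle in degrees (clockwise positive).
#' @param about `"center"` (default) or `"origin"`.
#' @return Image of the same shape.
#' @export
rotate_image <- function(img, theta_deg, about = c("center", "origin")) {
  about <- match.arg(about)
  stopifnot(is.finite(theta_deg))
  if (theta_deg == 0) return(img)
  d <- dim(img)
  flat <- length(d) == 2L
  if (flat) dim(img) <- c(d, 1L)
  H <- dim(img)[1L]; W <- dim(img)[2L]
  th <- theta_deg * pi / 180
  cy <- if (about == "center") (H - 1) / 2 else 0
  cx <- if (about == "center") (W - 1) / 2 else 0
  # visual coords: x right, y up; clockwise rotation by theta moves a point
  # at visual angle phi to phi - theta; sample the source by rotating the
  # destination coordinates back by +theta
  grid_c <- rep(0:(W - 1), each = H)
  grid_r <- rep(0:(H - 1), times = W)
  x <- grid_c - cx
  yv <- cy - grid_r
  xs <- x * cos(th) - yv * sin(th)
  ys <- x * sin(th) + yv * cos(th)
  src_r <- cy - ys
  src_c <- cx + xs
  out <- img
  for (c in seq_len(dim(img)[3L]))
    out[, , c] <- bilinear_sample(img[, , c], src_r, src_c)
  if (flat) dim(out) <- d
  out
}

#' Zoom an image
#'
#' Magnifies by `scale` on a canvas of unchanged size. `anchor = "origin"`
#' is the literal index-mapping reading `out[m, n] = in(floor(m/scale),
#' floor(n/scale))` with nearest-neighbor semantics; `anchor = "center"`
#' (the pipeline default) magnifies about the image center with bilinear
#' interpolation so the cell stays framed.
#'
#' @param img an (H, W) matrix or (H, W, C) array.
#' @param scale magnification factor (> 0).
#' @param anchor `"center"` (default) or `"origin"`.
#' @return Image of the same shape.
#' @export
zoom_image <- function(img, scale, anchor = c("center", "origin")) {
  anchor <- match.arg(anchor)
  stopifnot(scale > 0)
  if (scale == 1) return(img)
  d <- dim(img)
  flat <- length(d) == 2L
  if (flat) dim(img) <- c(d, 1L)
  H <- dim(img)[1L]; W <- dim(img)[2L]
  out <- img
  if (anchor == "origin") {
    sr <- pmin(floor((0:(H - 1)) / scale), H - 1) + 1L
    sc <- pmin(floor((0:(W - 1)) / scale), W - 1) + 1L
    out <- img[sr, sc, , drop = FALSE]
  } else {
    cy <- (H - 1) / 2; cx <- (W - 1) / 2
    grid_c <- rep(0:(W - 1), each = H)
    grid_r <- rep(0:(H - 1), times = W)
    src_r <- cy + (grid_r - cy) / scale
    src_c <- cx + (grid_c - cx) / scale
    for (c in seq_len(dim(img)[3L]))
      out[, , c] <- bilinear_sample(img[, , c], src_r, src_c)
  }
  if (flat) dim(out) <- d
  out
}

#' Random contrast enhancement
#'
#' Mean-anchored linear stretch: with factor `f` drawn uniformly from
#' `spec$contrast_range`, `out = clip((in - mean(in)) * f + mean(in), 0, 1)`.
#' The per-image mean is preserved before clipping; `f = 1` is the
#' identity.
#'
#' @param img image with values in \[0, 1\].
#' @param spec an [augmentation_spec()] (only `contrast_range` is used).
#' @param factor optional fixed factor overriding the random draw.
#' @return Image of the same shape with values in \[0, 1\].
#' @export
random_contrast <- function(img, spec = augmentation_spec(), factor = NULL) {
  f <- if (is.null(factor))
    runif(1L, spec$contrast_range[1L], spec$contrast_range[2L]) else factor
  mu <- mean(img)
  out <- (img - mu) * f + mu
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

enabled_transforms <- function(spec) {
  en <- character()
  if (spec$flip_enabled) en <- c(en, "flip")
  if (spec$rotation_deg != 0) en <- c(en, "rotate")
  if (spec$zoom_scale != 1) en <- c(en, "zoom")
  if (!(spec$contrast_range[1L] == 1 && spec$contrast_range[2L] == 1))
    en <- c(en, "contrast")
  en
}

image_signature <- function(img) {
  v <- as.numeric(img)
  paste(c(dim(img),
          sprintf("%.12g", c(sum(v), sum(v * v),
                             v[seq(1L, length(v), length.out = 16L)]))),
        collapse = "|")
}

apply_random_pipeline <- function(img, spec, chosen) {
  # fixed application order; parameters drawn per call
  if ("flip" %in% chosen) img <- flip_horizontal(img)
  if ("rotate" %in% chosen)
    img <- rotate_image(img, sample(c(-1, 1), 1L) * spec$rotation_deg)
  if ("zoom" %in% chosen) img <- zoom_image(img, spec$zoom_scale)
  if ("contrast" %in% chosen) img <- random_contrast(img, spec)
  img
}

#' Class-balancing augmentation
#'
#' Expands every class inside one split to exactly `target_per_class`
#' images. All originals are retained (a target below an original class
#' count is an error); each synthesized image is a composition of the
#' enabled transforms (never a crop) applied to a randomly chosen original
#' of the class. The sampler avoids emitting an image identical to one
#' already present while novel images remain reachable. Fully deterministic
#' under `spec$seed`.
#'
#' @param data a [labeled_image_set()].
#' @param target_per_class images per class after balancing; must be at
#'   least the largest original class count within the split.
#' @param spec an [augmentation_spec()] with at least one enabled transform.
#' @param split which split tag to balance (default `"train"`); images in
#'   other splits pass through untouched. When `data` carries no split
#'   tags, the whole set is balanced.
#' @return A new `labeled_image_set`; synthesized entries carry provenance
#'   `"augmented"` and inherit label and split from their source image.
#' @export
balance_augment <- function(data, target_per_class, spec, split = "train") {
  stopifnot(inherits(data, "cell_image_set"),
            inherits(spec, "augmentation_spec"))
  en <- enabled_transforms(spec)
  if (length(en) == 0L) stop("no augmentation transform is enabled")
  has_split <- !is.null(data$split)
  in_scope <- if (has_split) data$split == split else
    rep(TRUE, length(data$images))
  if (!any(in_scope)) stop(sprintf("split '%s' is empty", split))

  classes <- levels(data$labels)
  counts <- table(factor(data$labels[in_scope], levels = classes))
  if (any(counts == 0L))
    stop("every class must be non-empty before balancing")
  if (target_per_class < max(counts))
    stop(sprintf(
      "target_per_class (%d) is below the largest class count (%d); originals are never discarded",
      as.integer(target_per_class), max(counts)))

  set.seed(spec$seed)
  new_images <- list(); new_labels <- character()
  new_split <- character(); new_geom <- list()
  seen <- new.env(parent = emptyenv())
  for (i in which(in_scope))
    assign(image_signature(data$images[[i]]), TRUE, envir = seen)

  for (cl in classes) {
    pool <- which(in_scope & data$labels == cl)
    need <- as.integer(target_per_class) - length(pool)
    for (k in seq_len(max(0L, need))) {
      img <- NULL
      for (try in seq_len(25L)) {
        src <- pool[sample.int(length(pool), 1L)]
        nsub <- sample.int(length(en), 1L)
        chosen <- en[sample.int(length(en), nsub)]
        cand <- apply_random_pipeline(data$images[[src]], spec, chosen)
        sig <- image_signature(cand)
        if (!exists(sig, envir = seen, inherits = FALSE)) {
          assign(sig, TRUE, envir = seen)
          img <- cand
          break
        }
        if (try == 25L) img <- cand   # transform group exhausted
      }
      new_images[[length(new_images) + 1L]] <- img
      new_labels <- c(new_labels, cl)
      new_split <- c(new_split, if (has_split) split else NA_character_)
      new_geom[[length(new_geom) + 1L]] <-
        if (!is.null(data$geometry)) data$geometry[[src]] else NULL
    }
  }

  labeled_image_set(
    images = c(data$images, new_images),
    labels = factor(c(as.character(data$labels), new_labels),
                    levels = classes),
    split = if (has_split) c(as.character(data$split), new_split) else NULL,
    provenance = c(as.character(data$provenance %||%
                                  rep("original", length(data$images))),
                   rep("augmented", length(new_images))),
    geometry = if (!is.null(data$geometry)) c(data$geometry, new_geom) else
      NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
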