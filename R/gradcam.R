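# Grad-CAM and intermediate feature-map visualization.

default_cam_layer <- function(cfg) {
  if (cfg$use_drdb) "drdb" else if (cfg$use_glfeb) "glfeb" else "stem"
}

gradcam_layers <- function(cfg) {
  c("stem",
    if (cfg$use_drdb) "drdb",
    if (cfg$use_glfeb) "glfeb",
    if (cfg$use_csab) "csab",
    "fusion")
}

#' Grad-CAM class-activation heatmap
#'
#' Canonical gradient-weighted class activation mapping: the gradient of
#' the target-class logit with respect to a named convolutional stage's
#' activation is averaged over the spatial locations to give one weight per
#' channel; the heatmap is the ReLU of the weight-summed activation,
#' bilinearly upsampled to the input resolution and max-normalized to
#' \[0, 1\] when nonzero.
#'
#' @param model a `ddrnet_model`.
#' @param image an (H, W, C) image matching the model input size.
#' @param target_class class name or index whose score is explained.
#' @param layer named stage: one of `"stem"`, `"drdb"`, `"glfeb"`,
#'   `"csab"`, `"fusion"`. The default is the deepest residual convolution
#'   stage (`"drdb"` when present): the spatial attention map is normalized
#'   to sum to 1, which scales the attention output far below the fused
#'   convolution path, so the post-fusion activation carries little of the
#'   attention signal and the residual stage shows the clearest
#'   class-discriminative localization.
#' @return An object of class `cam_heatmap`: list with `values` (H x W
#'   non-negative matrix), `target_class` and `source_layer`.
#' @export
grad_cam <- function(model, image, target_class, layer = NULL) {
  if (is.null(layer)) layer <- default_cam_layer(model$config)
  avail <- gradcam_layers(model$config)
  if (!layer %in% avail)
    stop(sprintf("unknown layer '%s'; available layers: %s", layer,
                 paste(avail, collapse = ", ")))
  classes <- class_names_for(model$config$num_classes)
  k <- if (is.character(target_class)) match(target_class, classes) else
    as.integer(target_class)
  if (is.na(k) || k < 1L || k > length(classes))
    stop("unknown target class: ", target_class)

  fwd <- net_fwd(model, image, "eval", keep_acts = TRUE)
  dlogits <- matrix(0, model$config$num_classes, 1L)
  dlogits[k, 1L] <- 1
  bwd <- net_bwd(model, fwd$caches, dlogits, taps = layer)

  act <- fwd$acts[[layer]]          # (h, w, C, 1)
  grd <- bwd$taps[[layer]]
  d <- dim(act)
  am <- act; dim(am) <- c(d[1L] * d[2L], d[3L])
  gm <- grd; dim(gm) <- c(d[1L] * d[2L], d[3L])
  wts <- .colMeans(gm, d[1L] * d[2L], d[3L])   # spatial mean of d(score)/dA
  cam <- matrix(am %*% wts, d[1L], d[2L])
  cam[cam < 0] <- 0
  din <- dim(as_batch(image))
  cam <- resize_bilinear(cam, din[1L], din[2L])
  cam[cam < 0] <- 0                 # interpolation cannot add signal
  if (max(cam) > 0) cam <- cam / max(cam)
  structure(list(values = cam, target_class = classes[k],
                 source_layer = layer),
            class = "cam_heatmap")
}

#' @export
print.cam_heatmap <- function(x, ...) {
  cat(sprintf("Grad-CAM heatmap (%dx%d) for class '%s' at layer '%s'\n",
              nrow(x$values), ncol(x$values), x$target_class,
              x$source_layer))
  invisible(x)
}

#' Overlay a heatmap on its source image
#'
#' Simple fixed red-colormap alpha blend, for writing PNG overlays.
#'
#' @param image the (H, W, 3) source image.
#' @param cam a `cam_heatmap`.
#' @param alpha blend weight of the heatmap (default 0.45).
#' @return (H, W, 3) array in \[0, 1\].
#' @export
cam_overlay <- function(image, cam, alpha = 0.45) {
  h <- cam$values
  col <- array(0, dim = dim(image))
  col[, , 1] <- h
  col[, , 2] <- 0.2 * h
  col[, , 3] <- 1 - h
  out <- (1 - alpha) * image + alpha * col
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}

#' Tiled visualization of a stage's feature maps
#'
#' Extracts the activation of a named stage for one image, min-max scales
#' each channel independently (a constant channel becomes uniform gray) and
#' tiles at most `max_maps` channels into one grayscale grid image.
#'
#' @param model a `ddrnet_model`.
#' @param image an (H, W, C) image.
#' @param layer stage name as in [grad_cam()].
#' @param max_maps maximum number of channel tiles (default 64).
#' @param pad gap in pixels between tiles.
#' @return A matrix in \[0, 1\] (the grid image) with attribute
#'   `"tiles"` = number of tiles and `"tile_dim"` = each tile's (h, w).
#' @export
feature_map_grid <- function(model, image, layer = "stem", max_maps = 64L,
                             pad = 2L) {
  avail <- gradcam_layers(model$config)
  if (!layer %in% avail)
    stop(sprintf("unknown layer '%s'; available layers: %s", layer,
                 paste(avail, collapse = ", ")))
  fwd <- net_fwd(model, image, "eval", keep_acts = TRUE)
  act <- drop_batch(fwd$acts[[layer]])
  k <- min(dim(act)[3L], max_maps)
  h <- dim(act)[1L]; w <- dim(act)[2L]
  ncol_g <- ceiling(sqrt(k))
  nrow_g <- ceiling(k / ncol_g)
  grid <- matrix(0, nrow_g * h + (nrow_g - 1L) * pad,
                 ncol_g * w + (ncol_g - 1L) * pad)
  for (i in seq_len(k)) {
    ch <- act[, , i]
    rng <- range(ch)
    tile <- if (rng[2L] > rng[1L]) (ch - rng[1L]) / (rng[2L] - rng[1L]) else
      matrix(0.5, h, w)
    r0 <- ((i - 1L) %/% ncol_g) * (h + pad)
    c0 <- ((i - 1L) %% ncol_g) * (w + pad)
    grid[r0 + seq_len(h), c0 + seq_len(w)] <- tile
  }
  structure(grid, tiles = k, tile_dim = c(h, w))
}
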