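# User-facing forward operations for the individual network blocks. These
# accept a single feature map as an (H, W, C) array (a batch axis is also
# allowed) and wrap the same internals the end-to-end network uses, so the
# composed network is exactly the composition of these blocks.

#' Group normalization
#'
#' Splits the channels of a feature map into `num_groups` groups and
#' normalizes each group of every sample to zero mean and unit variance over
#' its (channels-in-group x height x width) elements, then applies the
#' per-channel affine transform `gamma * xhat + beta`.
#'
#' @param x an (H, W, C) or (H, W, C, N) array.
#' @param num_groups number of channel groups; must divide C.
#' @param gamma,beta per-channel scale and shift (default unit/zero).
#' @param eps variance floor (> 0, default 1e-5).
#' @return Array of the same shape as `x`.
#' @export
group_normalize <- function(x, num_groups, gamma = NULL, beta = NULL,
                            eps = 1e-5) {
  stopifnot(eps > 0)
  xb <- as_batch(x)
  C <- dim(xb)[3L]
  if (C %% num_groups != 0L)
    stop(sprintf(
      "group normalization: %d channels are not divisible by %d groups",
      C, as.integer(num_groups)))
  if (is.null(gamma)) gamma <- rep(1, C)
  if (is.null(beta)) beta <- rep(0, C)
  y <- gn_fwd(xb, num_groups, gamma, beta, eps)$y
  if (length(dim(x)) == 3L) drop_batch(y) else y
}

#' Stem convolution block
#'
#' 3x3 convolution to `stem_channels` filters, 2x2/stride-2 max pooling,
#' group normalization, ReLU.
#'
#' @param image an (H, W, C) image array matching `cfg$input_size`.
#' @param cfg a [model_config()].
#' @param params the model's stem parameters (`model$params$stem`).
#' @return (H/2, W/2, stem_channels) feature map, all entries >= 0.
#' @export
conv_stem_forward <- function(image, cfg, params) {
  xb <- as_batch(image)
  if (dim(xb)[3L] != cfg$input_size[3L])
    stop(sprintf("stem expects %d input channels, got %d",
                 cfg$input_size[3L], dim(xb)[3L]))
  y <- stem_fwd(xb, params, cfg$gn_groups)$y
  if (length(dim(image)) == 3L) drop_batch(y) else y
}

#' Residual convolution branches
#'
#' A residual branch computes `x + T(x)` where `T` is the chain
#' convolution, group normalization, ReLU, convolution, group
#' normalization; the dilated variant uses the same chain with dilated 3x3
#' convolutions (padding = dilation, so the output keeps the input shape).
#'
#' @param x an (H, W, C) or (H, W, C, N) feature map whose channel count
#'   equals the branch width.
#' @param params branch parameters: a list with `conv1`, `gn1`, `conv2`,
#'   `gn2` (see [ddrnet_init()]).
#' @param groups group-normalization group count (default 32).
#' @return Feature map of the same shape as `x`.
#' @export
residual_plain_branch <- function(x, params, groups = 32L) {
  residual_dilated_branch(x, 1L, params, groups)
}

#' @rdname residual_plain_branch
#' @param dilation positive integer dilation of both 3x3 convolutions.
#' @export
residual_dilated_branch <- function(x, dilation, params, groups = 32L) {
  if (length(dilation) != 1L || dilation < 1L)
    stop("dilation must be a positive integer")
  xb <- as_batch(x)
  y <- branch_fwd(xb, params, groups, dilation = as.integer(dilation))$y
  if (length(dim(x)) == 3L) drop_batch(y) else y
}

#' Dilated residual block (DRDB) forward pass
#'
#' Projects the input to the branch width, runs six parallel residual
#' branches (plain at positions 1, 3, 5; dilated at 2, 4, 6 with the
#' configured dilation sequence), concatenates the six outputs along the
#' channel axis (6 x branch width channels) and reduces them with a final
#' 1x1 convolution followed by group normalization and ReLU.
#'
#' @param x input feature map, (H, W, C) or batched.
#' @param cfg a [model_config()].
#' @param params one DRDB stage's parameters (`model$params$drdb[[1]]`).
#' @return Feature map with `cfg$drdb_branch_width` channels and the input
#'   spatial dimensions; the pre-reduction concatenation width is attached
#'   as attribute `"concat_width"`.
#' @export
drdb_forward <- function(x, cfg, params) {
  xb <- as_batch(x)
  stg <- drdb_stage_fwd(xb, params, cfg$gn_groups)
  y <- if (length(dim(x)) == 3L) drop_batch(stg$y) else stg$y
  attr(y, "concat_width") <- stg$concat_width
  y
}

#' Global/local feature enhancement block (GLFEB) forward pass
#'
#' The local path runs three convolution + group normalization + ReLU
#' layers over the residual-block output; the global path resamples the
#' stem feature to the local path's spatial size (bilinear) and projects it
#' to the same channel count c. Both are concatenated (2c channels) and
#' passed through tanh, so every output entry lies strictly in (-1, 1).
#'
#' @param global_feature the stem output feature map.
#' @param local_feature the residual-block output feature map.
#' @param cfg a [model_config()].
#' @param params `model$params$glfeb`.
#' @return Feature map with `2 * cfg$glfeb_widths[3]` channels; the local
#'   convolution output (pre-concatenation) is attached as attribute
#'   `"local_out"`.
#' @export
glfeb_forward <- function(global_feature, local_feature, cfg, params) {
  gb <- as_batch(global_feature)
  lb <- as_batch(local_feature)
  if (dim(gb)[4L] != dim(lb)[4L])
    stop("global and local features must share the batch size")
  gl <- glfeb_stage_fwd(gb, lb, params, cfg$gn_groups)
  y <- if (length(dim(local_feature)) == 3L) drop_batch(gl$y) else gl$y
  attr(y, "local_out") <-
    if (length(dim(local_feature)) == 3L) drop_batch(gl$local_out) else
      gl$local_out
  y
}

#' Global average pooling
#'
#' Averages each channel over all spatial locations.
#'
#' @param at an (H, W, C) or (H, W, C, N) feature map with H, W >= 1.
#' @return For a single map, a length-C vector; for a batch, a (C, N)
#'   matrix.
#' @export
global_average_pool <- function(at) {
  xb <- as_batch(at)
  if (dim(xb)[1L] < 1L || dim(xb)[2L] < 1L)
    stop("feature map has empty spatial extent")
  v <- gap_fwd(xb)$y
  if (length(dim(at)) == 3L) as.numeric(v) else v
}

#' Channel attention weights
#'
#' Global average pooling and global max pooling each feed a shared
#' two-layer bottleneck (linear, ReLU, linear); the two outputs are summed
#' and passed through a sigmoid, giving one gating weight per channel in
#' (0, 1).
#'
#' @param at feature map, (H, W, C) or batched.
#' @param params `model$params$csab` (uses `ca1`, `ca2`).
#' @return Per-channel weight vector (or (C, N) matrix for a batch), every
#'   entry strictly in (0, 1).
#' @export
channel_attention <- function(at, params) {
  xb <- as_batch(at)
  if (ncol(params$ca1$W) != dim(xb)[3L])
    stop(sprintf("attention parameters expect %d channels, got %d",
                 ncol(params$ca1$W), dim(xb)[3L]))
  qc <- ca_fwd(xb, params)$qc
  if (length(dim(at)) == 3L) as.numeric(qc) else qc
}

#' Spatial attention map
#'
#' A 5x5 convolution collapses the channels to a single map, ReLU clamps it
#' to be non-negative, and the map is normalized to sum to 1 over all its
#' entries. An all-zero pre-normalization map degenerates; a uniform map is
#' returned with a warning.
#'
#' @param at feature map, (H, W, C) or batched.
#' @param params `model$params$csab` (uses `sa`).
#' @return (H, W) matrix (or (H, W, 1, N) array for a batch) of
#'   non-negative weights summing to 1 per sample.
#' @export
spatial_attention <- function(at, params) {
  xb <- as_batch(at)
  sa <- sa_fwd(xb, params)
  d <- sa$dims
  qs <- sa$qs
  dim(qs) <- d
  if (length(dim(at)) == 3L) matrix(qs, d[1L], d[2L]) else qs
}

#' Channel and spatial attention block (CSAB) forward pass
#'
#' Gates the input feature map with the channel attention weights and the
#' normalized spatial attention map:
#' `out[h, w, c] = at[h, w, c] * Qc[c] * Qs[h, w]`.
#'
#' @param at feature map, (H, W, C) or batched.
#' @param params `model$params$csab`.
#' @return Feature map of the same shape as `at`, with the attention
#'   factors attached as attributes `"qc"` and `"qs"`.
#' @export
csab_forward <- function(at, params) {
  xb <- as_batch(at)
  cs <- csab_stage_fwd(xb, params)
  y <- if (length(dim(at)) == 3L) drop_batch(cs$y) else cs$y
  attr(y, "qc") <- if (length(dim(at)) == 3L) as.numeric(cs$qc) else cs$qc
  attr(y, "qs") <- cs$qs
  y
}

#' End-to-end classifier forward pass
#'
#' Runs the full network on one image or a batch and returns class scores.
#' With the default softmax head the scores of each image are non-negative
#' and sum to 1; in `"eval"` mode the pass is deterministic (dropout off,
#' batch normalization using running statistics).
#'
#' @param model a `ddrnet_model`.
#' @param image an (H, W, C) image or (H, W, C, N) batch matching
#'   `model$config$input_size`.
#' @param mode `"eval"` (default) or `"train"`.
#' @return For one image, a named numeric vector of class scores; for a
#'   batch, a (num_classes, N) matrix.
#' @export
ddrnet_forward <- function(model, image, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  out <- net_fwd(model, image, mode)
  probs <- out$probs
  rownames(probs) <- class_names_for(model$config$num_classes)
  if (length(dim(image)) == 3L) probs[, 1L] else probs
}

class_names_for <- function(k) {
  if (k == length(CELL_CLASSES)) CELL_CLASSES else paste0("class", seq_len(k))
}
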