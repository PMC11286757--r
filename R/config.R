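#' Architectural configuration for a DDRNet classifier
#'
#' Records every width, dilation and switch the network is built from. The
#' defaults follow the reference recipe: a 32-filter 3x3 stem, a six-branch
#' dilated residual block with dilation sequence 1/2/4, global/local feature
#' enhancement widths (64, 128, 64), group normalization with 32 groups,
#' 20% dropout at the post-fusion stage, a 5x5 spatial-attention kernel and
#' a softmax head over the four leukocyte classes.
#'
#' @param input_size integer vector `(H, W, C)`; images are resized to this
#'   before entering the network. Default `c(224, 224, 3)`.
#' @param stem_channels filters in the stem convolution (default 32).
#' @param drdb_branch_width channel width of every residual branch inside the
#'   dilated residual block (default 64).
#' @param drdb_dilations dilation sequence of the three dilated branches;
#'   exactly three strictly increasing integers (default `c(1, 2, 4)`).
#' @param drdb_depth number of dilated residual stages stacked in sequence
#'   (default 1).
#' @param glfeb_widths the three convolution widths of the global/local
#'   feature enhancement block (default `c(64, 128, 64)`).
#' @param gn_groups group count for group normalization (default 32). When a
#'   layer's channel count is not divisible by this, the largest common
#'   divisor is used for that layer.
#' @param dropout_rate dropout applied after the post-fusion batch
#'   normalization, in `[0, 1)` (default 0.2).
#' @param num_classes number of output classes (default 4).
#' @param head `"softmax"` (mutually exclusive classes, the default) or
#'   `"sigmoid"` (independent per-class scores).
#' @param csab_kernel spatial-attention convolution kernel size (default 5).
#' @param attention_fc_reduction reduction ratio of the two-layer
#'   channel-attention bottleneck (default 8).
#' @param use_drdb,use_glfeb,use_csab block switches used by the ablation
#'   harness; all `TRUE` for the full network.
#' @return An object of class `ddrnet_config` (a validated list).
#' @export
model_config <- function(input_size = c(224L, 224L, 3L),
                         stem_channels = 32L,
                         drdb_branch_width = 64L,
                         drdb_dilations = c(1L, 2L, 4L),
                         drdb_depth = 1L,
                         glfeb_widths = c(64L, 128L, 64L),
                         gn_groups = 32L,
                         dropout_rate = 0.2,
                         num_classes = 4L,
                         head = c("softmax", "sigmoid"),
                         csab_kernel = 5L,
                         attention_fc_reduction = 8L,
                         use_drdb = TRUE,
                         use_glfeb = TRUE,
                         use_csab = TRUE) {
  head <- match.arg(head)
  cfg <- list(
    input_size = as.integer(input_size),
    stem_channels = as.integer(stem_channels),
    drdb_branch_width = as.integer(drdb_branch_width),
    drdb_dilations = as.integer(drdb_dilations),
    drdb_depth = as.integer(drdb_depth),
    glfeb_widths = as.integer(glfeb_widths),
    gn_groups = as.integer(gn_groups),
    dropout_rate = as.numeric(dropout_rate),
    num_classes = as.integer(num_classes),
    head = head,
    csab_kernel = as.integer(csab_kernel),
    attention_fc_reduction = as.integer(attention_fc_reduction),
    use_drdb = isTRUE(use_drdb),
    use_glfeb = isTRUE(use_glfeb),
    use_csab = isTRUE(use_csab)
  )
  validate_model_config(cfg)
  class(cfg) <- "ddrnet_config"
  cfg
}

validate_model_config <- function(cfg) {
  stopifnot(length(cfg$input_size) == 3L, all(cfg$input_size >= 1L))
  if (length(cfg$drdb_dilations) != 3L ||
      any(diff(cfg$drdb_dilations) <= 0L) || any(cfg$drdb_dilations < 1L))
    stop("drdb_dilations must be exactly 3 strictly increasing positive integers")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)")
  if (cfg$num_classes < 2L) stop("num_classes must be >= 2")
  if (length(cfg$glfeb_widths) != 3L || any(cfg$glfeb_widths < 1L))
    stop("glfeb_widths must be 3 positive integers")
  if (cfg$csab_kernel %% 2L != 1L) stop("csab_kernel must be odd")
  if (cfg$drdb_depth < 1L) stop("drdb_depth must be >= 1")
  invisible(cfg)
}

#' @export
print.ddrnet_config <- function(x, ...) {
  cat("DDRNet configuration\n")
  cat(sprintf("  input          %dx%dx%d\n", x$input_size[1], x$input_size[2],
              x$input_size[3]))
  cat(sprintf("  stem           %d filters, 3x3, max-pool 2x2\n",
              x$stem_channels))
  cat(sprintf("  DRDB           %s, width %d, dilations %s, depth %d\n",
              if (x$use_drdb) "on" else "off", x$drdb_branch_width,
              paste(x$drdb_dilations, collapse = "/"), x$drdb_depth))
  cat(sprintf("  GLFEB          %s, widths %s\n",
              if (x$use_glfeb) "on" else "off",
              paste(x$glfeb_widths, collapse = "/")))
  cat(sprintf("  CSAB           %s, %dx%d spatial kernel, reduction %d\n",
              if (x$use_csab) "on" else "off", x$csab_kernel, x$csab_kernel,
              x$attention_fc_reduction))
  cat(sprintf("  GN groups %d | dropout %.2f | head %s | classes %d\n",
              x$gn_groups, x$dropout_rate, x$head, x$num_classes))
  invisible(x)
}

#' Write / read a model or training configuration as YAML
#'
#' @param cfg a `ddrnet_config` or `ddrnet_train_config`.
#' @param path file path.
#' @return The `*_from_yaml()` readers return a validated configuration
#'   object.
#' @export
config_to_yaml <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname config_to_yaml
#' @export
config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(model_config, raw)
}

#' @rdname config_to_yaml
#' @export
train_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$optimizer <- NULL
  do.call(train_config, raw)
}

#' Training configuration
#'
#' The reference recipe: Adam with a constant learning rate of 0.01 for 30
#' epochs and 20% dropout. The batch size is left open by the
#' recipe; the back-calculation from the reported iteration count suggests
#' roughly 184 images per batch, but the default here is 32, which fits
#' desk-scale memory.
#'
#' @param learning_rate Adam step size (> 0, default 0.01).
#' @param epochs training epochs (default 30).
#' @param batch_size minibatch size (default 32).
#' @param seed integer seed controlling shuffling, initialization and dropout.
#' @param deterministic_mode when `TRUE` (default) the run is seeded
#'   end-to-end and bit-reproducible.
#' @param val_frac fraction of the training split carved off for validation
#'   tracking (0 keeps everything in train; validation metrics then fall back
#'   to the training split).
#' @return An object of class `ddrnet_train_config`.
#' @export
train_config <- function(learning_rate = 0.01, epochs = 30L, batch_size = 32L,
                         seed = 1L, deterministic_mode = TRUE,
                         val_frac = 0) {
  stopifnot(learning_rate > 0, epochs >= 1L, batch_size >= 1L,
            val_frac >= 0, val_frac < 1)
  structure(list(optimizer = "adam",
                 learning_rate = as.numeric(learning_rate),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 deterministic_mode = isTRUE(deterministic_mode),
                 val_frac = as.numeric(val_frac)),
            class = "ddrnet_train_config")
}

# group count actually used for a layer of C channels: the configured count
# when it divides C, otherwise gcd(configured, C) (never less than 1)
gn_groups_for <- function(C, groups) {
  if (C %% groups == 0L) return(as.integer(groups))
  g <- as.integer(groups); c2 <- as.integer(C)
  while (c2 != 0L) { t <- g %% c2; g <- c2; c2 <- t }
  max(1L, g)
}
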