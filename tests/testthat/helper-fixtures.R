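# Shared fixtures. Heavy artifacts (synthetic sets, trained models) are
# built lazily once per test session and cached in this environment.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

# the width-reduced configuration used for all desk-scale training runs
reduced_config <- function(...) {
  model_config(input_size = c(32L, 32L, 3L), stem_channels = 16L,
               drdb_branch_width = 16L, glfeb_widths = c(16L, 32L, 16L), ...)
}

# a tiny configuration for fast structural / gradient tests
tiny_config <- function(...) {
  model_config(input_size = c(8L, 8L, 3L), stem_channels = 4L,
               drdb_branch_width = 4L, glfeb_widths = c(4L, 6L, 4L),
               gn_groups = 2L, attention_fc_reduction = 2L, ...)
}

synth_set_400 <- function() {
  fixture("set400", function()
    split_train_test(
      generate_synthetic_cells(synthetic_cell_spec(seed = 42L),
                               n_per_class = 100L),
      train_frac = 0.8, seed = 42L))
}

# 40-image (10/class) overfit run used by the capacity and Grad-CAM checks
overfit_fit <- function() {
  fixture("overfit", function() {
    set40 <- generate_synthetic_cells(synthetic_cell_spec(seed = 42L),
                                      n_per_class = 10L)
    model <- ddrnet_init(reduced_config(), seed = 42L)
    fit <- train_model(model, set40, train_config(epochs = 50L, seed = 42L))
    fit$data <- set40
    fit
  })
}

big_fit <- function() {
  fixture("bigfit", function() {
    data <- synth_set_400()
    model <- ddrnet_init(reduced_config(), seed = 42L)
    fit <- train_model(model, data, train_config(epochs = 15L, seed = 42L))
    fit
  })
}

# independent brute-force group-normalization oracle: explicit loops over
# every group's member set
gn_oracle <- function(x, groups, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  cg <- C / groups
  out <- x
  for (n in seq_len(N)) {
    for (g in seq_len(groups)) {
      chans <- ((g - 1) * cg + 1):(g * cg)
      vals <- c()
      for (c in chans) for (i in seq_len(H)) for (j in seq_len(W))
        vals <- c(vals, x[i, j, c, n])
      mu <- sum(vals) / length(vals)
      v <- sum((vals - mu)^2) / length(vals)
      for (c in chans) for (i in seq_len(H)) for (j in seq_len(W))
        out[i, j, c, n] <-
          gamma[c] * (x[i, j, c, n] - mu) / sqrt(v + eps) + beta[c]
    }
  }
  if (length(dim(out)) == 4L && dim(out)[4L] == 1L)
    out <- array(out, dim = d[1:3])
  out
}

# naive same-size dilated convolution with edge-replicate padding
conv_oracle <- function(x, w, b, dilation = 1L) {
  d <- dim(x); kd <- dim(w)
  H <- d[1]; W <- d[2]; C <- d[3]
  kh <- kd[1]; kw <- kd[2]; Cout <- kd[4]
  ph <- dilation * (kh - 1) / 2; pw <- dilation * (kw - 1) / 2
  out <- array(0, dim = c(H, W, Cout))
  clamp <- function(v, hi) pmin(pmax(v, 1L), hi)
  for (o in seq_len(Cout)) for (i in seq_len(H)) for (j in seq_len(W)) {
    s <- b[o]
    for (c in seq_len(C)) for (di in seq_len(kh)) for (dj in seq_len(kw)) {
      ii <- clamp(i + (di - 1) * dilation - ph, H)
      jj <- clamp(j + (dj - 1) * dilation - pw, W)
      s <- s + x[ii, jj, c] * w[di, dj, c, o]
    }
    out[i, j, o] <- s
  }
  out
}

# naive bilinear resize matching the documented half-pixel-center mapping
resize_oracle <- function(img, oh, ow) {
  d <- dim(img)
  H <- d[1]; W <- d[2]
  out <- array(0, dim = c(oh, ow, d[3]))
  for (c in seq_len(d[3])) for (i in seq_len(oh)) for (j in seq_len(ow)) {
    sy <- min(max((i - 0.5) * H / oh - 0.5, 0), H - 1)
    sx <- min(max((j - 0.5) * W / ow - 0.5, 0), W - 1)
    y0 <- floor(sy); x0 <- floor(sx)
    y1 <- min(y0 + 1, H - 1); x1 <- min(x0 + 1, W - 1)
    fy <- sy - y0; fx <- sx - x0
    out[i, j, c] <-
      (1 - fy) * (1 - fx) * img[y0 + 1, x0 + 1, c] +
      (1 - fy) * fx * img[y0 + 1, x1 + 1, c] +
      fy * (1 - fx) * img[y1 + 1, x0 + 1, c] +
      fy * fx * img[y1 + 1, x1 + 1, c]
  }
  out
}

random_fmap <- function(H, W, C, N = NULL) {
  if (is.null(N)) array(rnorm(H * W * C), dim = c(H, W, C)) else
    array(rnorm(H * W * C * N), dim = c(H, W, C, N))
}

# peak-in-bounding-box check at the cam's native feature-grid resolution
cam_peak_in_bbox <- function(cam, bbox, canvas = 224L) {
  v <- cam$values
  side <- nrow(v)
  pk <- which(v == max(v), arr.ind = TRUE)[1L, ]
  r0 <- floor((bbox[["row_min"]] - 1) * side / canvas) + 1
  r1 <- ceiling(bbox[["row_max"]] * side / canvas)
  c0 <- floor((bbox[["col_min"]] - 1) * side / canvas) + 1
  c1 <- ceiling(bbox[["col_max"]] * side / canvas)
  pk[1L] >= r0 && pk[1L] <= r1 && pk[2L] >= c0 && pk[2L] <= c1
}
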