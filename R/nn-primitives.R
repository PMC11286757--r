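# Differentiable primitives. Every *_fwd returns list(y = output, cache = ...)
# and the matching *_bwd maps (cache, dy) to input/parameter gradients.
# Activation volumes are arrays in (H, W, C, N) layout; the heavy kernels
# (convolution, pooling, bilinear resampling) live in src/ops.cpp.

as_batch <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) < 3L || length(d) > 4L)
    stop("expected an (H, W, C) or (H, W, C, N) array")
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

drop_batch <- function(x) {
  d <- dim(x)
  if (length(d) == 4L && d[4L] == 1L) dim(x) <- d[1:3]
  x
}

conv_fwd <- function(x, W, b, dilation = 1L) {
  list(y = .conv2d_fwd(x, W, b, as.integer(dilation)),
       cache = list(x = x, W = W, dilation = as.integer(dilation)))
}

conv_bwd <- function(cache, dy) {
  g <- .conv2d_bwd(cache$x, cache$W, dy, cache$dilation)
  list(dx = g$dx, dW = g$dw, db = as.numeric(g$db))
}

pool_fwd <- function(x) {
  r <- .maxpool2_fwd(x)
  list(y = r$y, cache = list(idx = r$idx, xdim = dim(x)))
}

pool_bwd <- function(cache, dy) {
  .maxpool2_bwd(cache$idx, dy, as.integer(cache$xdim))
}

resize_fwd <- function(x, out_h, out_w) {
  d <- dim(x)
  if (d[1L] == out_h && d[2L] == out_w)
    return(list(y = x, cache = list(identity = TRUE)))
  list(y = .bilinear_fwd(x, as.integer(out_h), as.integer(out_w)),
       cache = list(identity = FALSE, in_h = d[1L], in_w = d[2L]))
}

resize_bwd <- function(cache, dy) {
  if (isTRUE(cache$identity)) return(dy)
  .bilinear_bwd(dy, as.integer(cache$in_h), as.integer(cache$in_w))
}

relu_fwd <- function(x) {
  mask <- x > 0
  list(y = x * mask, cache = mask)
}

relu_bwd <- function(mask, dy) dy * mask

tanh_fwd <- function(x) {
  y <- tanh(x)
  list(y = y, cache = y)
}

tanh_bwd <- function(y, dy) dy * (1 - y^2)

sigmoid <- function(x) 1 / (1 + exp(-x))

# --- group normalization ----------------------------------------------------
# Normalizes each (group of channels x H x W) slab of every sample to zero
# mean / unit variance, then applies a per-channel affine (gamma, beta).
# Channel layout makes each group a contiguous block of length H*W*(C/G).

gn_fwd <- function(x, groups, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  H <- d[1L]; W <- d[2L]; C <- d[3L]; N <- d[4L]
  G <- as.integer(groups)
  if (C %% G != 0L)
    stop(sprintf(
      "group normalization: %d channels are not divisible by %d groups", C, G))
  m <- H * W * (C %/% G)
  M <- x
  dim(M) <- c(m, G * N)
  mu <- .colMeans(M, m, G * N)
  ctr <- sweep(M, 2L, mu, `-`)
  v <- .colMeans(ctr * ctr, m, G * N)
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(ctr, 2L, inv, `*`)
  gs <- rep(gamma, times = N)
  bs <- rep(beta, times = N)
  y <- xhat
  dim(y) <- c(H * W, C * N)
  y <- sweep(y, 2L, gs, `*`)
  y <- sweep(y, 2L, bs, `+`)
  dim(y) <- d
  list(y = y,
       cache = list(xhat = xhat, inv = inv, gamma = gamma, dims = d, m = m))
}

gn_bwd <- function(cache, dy) {
  d <- cache$dims
  H <- d[1L]; W <- d[2L]; C <- d[3L]; N <- d[4L]
  m <- cache$m
  GN <- length(cache$inv)
  xhat <- cache$xhat

  dym <- dy
  dim(dym) <- c(H * W, C * N)
  xh2 <- xhat
  dim(xh2) <- c(H * W, C * N)
  dgamma <- rowSums(matrix(.colSums(dym * xh2, H * W, C * N), nrow = C))
  dbeta <- rowSums(matrix(.colSums(dym, H * W, C * N), nrow = C))

  dxhat <- sweep(dym, 2L, rep(cache$gamma, times = N), `*`)
  dim(dxhat) <- c(m, GN)
  mean_d <- .colMeans(dxhat, m, GN)
  mean_dx <- .colMeans(dxhat * xhat, m, GN)
  dx <- dxhat - rep(mean_d, each = m) - xhat * rep(mean_dx, each = m)
  dx <- sweep(dx, 2L, cache$inv, `*`)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# --- batch normalization (post-fusion stage only) ---------------------------
# Per-channel statistics over (H, W, N); running estimates for eval mode.

bn_fwd <- function(x, gamma, beta, run_mean, run_var, mode, momentum = 0.1,
                   eps = 1e-5) {
  d <- dim(x)
  H <- d[1L]; W <- d[2L]; C <- d[3L]; N <- d[4L]
  if (mode == "train") {
    xp <- aperm(x, c(1L, 2L, 4L, 3L))
    dim(xp) <- c(H * W * N, C)
    mu <- .colMeans(xp, H * W * N, C)
    ctr <- sweep(xp, 2L, mu, `-`)
    v <- .colMeans(ctr * ctr, H * W * N, C)
    inv <- 1 / sqrt(v + eps)
    xhat <- sweep(ctr, 2L, inv, `*`)
    y <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
    dim(y) <- c(H, W, N, C)
    y <- aperm(y, c(1L, 2L, 4L, 3L))
    new_mean <- (1 - momentum) * run_mean + momentum * mu
    new_var <- (1 - momentum) * run_var + momentum * v
    list(y = y,
         cache = list(xhat = xhat, inv = inv, gamma = gamma, dims = d),
         run_mean = new_mean, run_var = new_var)
  } else {
    inv <- 1 / sqrt(run_var + eps)
    scale <- gamma * inv
    shift <- beta - run_mean * scale
    y <- x
    dim(y) <- c(H * W, C * N)
    y <- sweep(y, 2L, rep(scale, times = N), `*`)
    y <- sweep(y, 2L, rep(shift, times = N), `+`)
    dim(y) <- d
    list(y = y, cache = NULL, run_mean = run_mean, run_var = run_var)
  }
}

bn_bwd <- function(cache, dy) {
  d <- cache$dims
  H <- d[1L]; W <- d[2L]; C <- d[3L]; N <- d[4L]
  m <- H * W * N
  dyp <- aperm(dy, c(1L, 2L, 4L, 3L))
  dim(dyp) <- c(m, C)
  xhat <- cache$xhat
  dgamma <- .colSums(dyp * xhat, m, C)
  dbeta <- .colSums(dyp, m, C)
  dxhat <- sweep(dyp, 2L, cache$gamma, `*`)
  dx <- dxhat -
    rep(.colMeans(dxhat, m, C), each = m) -
    xhat * rep(.colMeans(dxhat * xhat, m, C), each = m)
  dx <- sweep(dx, 2L, cache$inv, `*`)
  dim(dx) <- c(H, W, N, C)
  dx <- aperm(dx, c(1L, 2L, 4L, 3L))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# --- dense / pooling heads --------------------------------------------------

dense_fwd <- function(x, W, b) {
  # x: (In, N) matrix
  list(y = W %*% x + b, cache = list(x = x, W = W))
}

dense_bwd <- function(cache, dy) {
  list(dx = crossprod(cache$W, dy),
       dW = tcrossprod(dy, cache$x),
       db = rowSums(dy))
}

gap_fwd <- function(x) {
  d <- dim(x)
  hw <- d[1L] * d[2L]
  m <- x
  dim(m) <- c(hw, d[3L] * d[4L])
  v <- matrix(.colMeans(m, hw, d[3L] * d[4L]), nrow = d[3L])
  list(y = v, cache = d)   # (C, N)
}

gap_bwd <- function(dims, dy) {
  hw <- dims[1L] * dims[2L]
  dx <- rep(as.numeric(dy) / hw, each = hw)
  dim(dx) <- dims
  dx
}

gmp_fwd <- function(x) {
  d <- dim(x)
  hw <- d[1L] * d[2L]
  m <- x
  dim(m) <- c(hw, d[3L] * d[4L])
  idx <- max.col(t(m), ties.method = "first")   # argmax per column
  v <- matrix(m[cbind(idx, seq_along(idx))], nrow = d[3L])
  list(y = v, cache = list(idx = idx, dims = d))
}

gmp_bwd <- function(cache, dy) {
  d <- cache$dims
  hw <- d[1L] * d[2L]
  dx <- matrix(0, hw, d[3L] * d[4L])
  dx[cbind(cache$idx, seq_along(cache$idx))] <- as.numeric(dy)
  dim(dx) <- d
  dx
}

dropout_fwd <- function(x, rate, mode) {
  if (mode != "train" || rate <= 0)
    return(list(y = x, cache = NULL))
  keep <- (runif(length(x)) >= rate) / (1 - rate)
  dim(keep) <- dim(x)
  list(y = x * keep, cache = keep)
}

dropout_bwd <- function(cache, dy) {
  if (is.null(cache)) dy else dy * cache
}

# --- losses -----------------------------------------------------------------

softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max), `-`)
  e <- exp(z)
  sweep(e, 2L, colSums(e), `/`)
}

# Mean cross-entropy over the batch; grad w.r.t. logits.
softmax_ce <- function(logits, onehot) {
  p <- softmax_cols(logits)
  n <- ncol(logits)
  loss <- -sum(onehot * log(pmax(p, 1e-12))) / n
  list(loss = loss, probs = p, dlogits = (p - onehot) / n)
}

sigmoid_bce <- function(logits, onehot) {
  p <- sigmoid(logits)
  n <- ncol(logits)
  loss <- -sum(onehot * log(pmax(p, 1e-12)) +
                 (1 - onehot) * log(pmax(1 - p, 1e-12))) / (n * nrow(logits))
  list(loss = loss, probs = p, dlogits = (p - onehot) / (n * nrow(logits)))
}
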