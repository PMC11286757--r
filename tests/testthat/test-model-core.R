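# Structural and oracle tests for the network blocks.

test_that("stem halves the spatial dims, widens to stem_channels and is non-negative", {
  cfg <- model_config(input_size = c(224, 224, 3))
  model <- ddrnet_init(cfg, seed = 1)
  img <- array(runif(224 * 224 * 3), dim = c(224, 224, 3))
  out <- conv_stem_forward(img, cfg, model$params$stem)
  expect_identical(dim(out), c(112L, 112L, 32L))
  expect_gte(min(out), 0)
  expect_error(conv_stem_forward(array(0, dim = c(224, 224, 4)), cfg,
                                 model$params$stem),
               "3 input channels")
})

test_that("stem equals the composition of conv, max-pool, group-norm and ReLU", {
  cfg <- tiny_config()
  model <- ddrnet_init(cfg, seed = 2)
  set.seed(3)
  img <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
  p <- model$params$stem
  cv <- conv_oracle(img, p$conv$W, p$conv$b)
  pooled <- array(0, dim = c(4, 4, dim(cv)[3]))
  for (c in seq_len(dim(cv)[3])) for (i in 1:4) for (j in 1:4)
    pooled[i, j, c] <- max(cv[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c])
  gn <- gn_oracle(pooled, ddrnet:::gn_groups_for(4L, cfg$gn_groups),
                  p$gn$gamma, p$gn$beta)
  expect_equal(conv_stem_forward(img, cfg, p), pmax(gn, 0),
               tolerance = 1e-5)
})

test_that("residual branches reduce to the skip path when the final gain is zero", {
  cfg <- tiny_config()
  model <- ddrnet_init(cfg, seed = 4)
  p <- model$params$drdb[[1]]$branches[[2]]
  p$gn2$gamma <- rep(0, 4)
  set.seed(5)
  x <- random_fmap(6, 6, 4)
  expect_equal(residual_dilated_branch(x, 2, p, groups = 2), x)
  expect_identical(dim(residual_plain_branch(x, p, groups = 2)), dim(x))
})

test_that("a residual branch equals x plus its hand-composed transform chain", {
  cfg <- tiny_config()
  model <- ddrnet_init(cfg, seed = 6)
  p <- model$params$drdb[[1]]$branches[[1]]
  set.seed(7)
  x <- random_fmap(5, 5, 4)
  t1 <- gn_oracle(conv_oracle(x, p$conv1$W, p$conv1$b), 2, p$gn1$gamma,
                  p$gn1$beta)
  t2 <- gn_oracle(conv_oracle(pmax(t1, 0), p$conv2$W, p$conv2$b), 2,
                  p$gn2$gamma, p$gn2$beta)
  expect_equal(residual_plain_branch(x, p, groups = 2), x + t2,
               tolerance = 1e-5)
})

test_that("a dilation-1 dilated branch reproduces the plain branch on identical weights", {
  model <- ddrnet_init(tiny_config(), seed = 8)
  p <- model$params$drdb[[1]]$branches[[1]]
  set.seed(9)
  x <- random_fmap(6, 6, 4)
  expect_equal(residual_dilated_branch(x, 1, p, groups = 2),
               residual_plain_branch(x, p, groups = 2))
})

test_that("a zero volume through a zero-bias branch transform stays zero", {
  model <- ddrnet_init(tiny_config(), seed = 10)
  p <- model$params$drdb[[1]]$branches[[4]]
  x <- array(0, dim = c(6, 6, 4))
  expect_equal(residual_dilated_branch(x, 2, p, groups = 2), x)
})

test_that("dilated 3x3 gradient probes span 3, 5 and 9 pixels on the dilation lattice", {
  for (d in c(1L, 2L, 4L)) {
    H <- 21L
    x <- array(0, dim = c(H, H, 1L, 1L))
    w <- array(1, dim = c(3L, 3L, 1L, 1L))
    dy <- array(0, dim = c(H, H, 1L, 1L))
    ctr <- 11L
    dy[ctr, ctr, 1, 1] <- 1
    g <- ddrnet:::.conv2d_bwd(x, w, dy, d)$dx[, , 1, 1]
    nz <- which(g != 0, arr.ind = TRUE)
    span <- as.integer(3 + 2 * (d - 1))
    expect_identical(diff(range(nz[, 1])) + 1L, span)
    expect_identical(diff(range(nz[, 2])) + 1L, span)
    # taps sit on a dilation-spaced lattice around the probed pixel
    expect_true(all((nz[, 1] - ctr) %% d == 0))
    expect_true(all((nz[, 2] - ctr) %% d == 0))
    expect_identical(nrow(nz), 9L)
  }
})

test_that("DRDB concatenates six branch-width features and preserves spatial dims", {
  cfg <- tiny_config()
  model <- ddrnet_init(cfg, seed = 11)
  set.seed(12)
  x <- random_fmap(6, 6, cfg$stem_channels)
  out <- drdb_forward(x, cfg, model$params$drdb[[1]])
  expect_identical(attr(out, "concat_width"), 6L * cfg$drdb_branch_width)
  expect_identical(dim(out)[1:2], dim(x)[1:2])
  expect_identical(dim(out)[3], cfg$drdb_branch_width)
})

test_that("DRDB equals the hand-composed projection/branch/concat/reduce chain", {
  cfg <- tiny_config()
  model <- ddrnet_init(cfg, seed = 13)
  p <- model$params$drdb[[1]]
  set.seed(14)
  x <- random_fmap(5, 5, cfg$stem_channels)
  xp <- conv_oracle(x, p$proj$W, p$proj$b)
  dil6 <- ddrnet:::branch_dilations(cfg)
  outs <- lapply(seq_len(6), function(k)
    residual_dilated_branch(xp, dil6[k], p$branches[[k]],
                            groups = cfg$gn_groups))
  cat6 <- array(0, dim = c(5, 5, 24))
  for (k in seq_len(6)) cat6[, , (4 * k - 3):(4 * k)] <- outs[[k]]
  red <- conv_oracle(cat6, p$fuse$W, p$fuse$b)
  red <- gn_oracle(red, ddrnet:::gn_groups_for(4L, cfg$gn_groups),
                   p$fuse_gn$gamma, p$fuse_gn$beta)
  expect_equal(as.numeric(drdb_forward(x, cfg, p)),
               as.numeric(pmax(red, 0)), tolerance = 1e-5)
})

test_that("zeroing the reduction weights of branches 2-6 isolates branch 1", {
  cfg <- tiny_config()
  model <- ddrnet_init(cfg, seed = 15)
  p <- model$params$drdb[[1]]
  p$fuse$W[, , 5:24, ] <- 0   # keep only branch 1's channels in the reduction
  set.seed(16)
  x <- random_fmap(5, 5, cfg$stem_channels)
  xp <- conv_oracle(x, p$proj$W, p$proj$b)
  b1 <- residual_plain_branch(xp, p$branches[[1]], groups = cfg$gn_groups)
  padded <- array(0, dim = c(5, 5, 24))
  padded[, , 1:4] <- b1
  red <- gn_oracle(conv_oracle(padded, p$fuse$W, p$fuse$b),
                   ddrnet:::gn_groups_for(4L, cfg$gn_groups),
                   p$fuse_gn$gamma, p$fuse_gn$beta)
  expect_equal(as.numeric(drdb_forward(x, cfg, p)),
               as.numeric(pmax(red, 0)), tolerance = 1e-5)
})

test_that("GLFEB doubles the channel count, bounds outputs in (-1, 1) and is odd in its pre-activation", {
  cfg <- tiny_config()
  model <- ddrnet_init(cfg, seed = 17)
  p <- model$params$glfeb
  set.seed(18)
  g <- random_fmap(6, 6, cfg$stem_channels)
  l <- random_fmap(6, 6, cfg$drdb_branch_width)
  out <- glfeb_forward(g, l, cfg, p)
  expect_identical(dim(out)[3], 2L * cfg$glfeb_widths[3])
  expect_lt(max(abs(out)), 1)

  # reconstruct the pre-activation from the attached local path and the
  # projected global path; tanh of it must give the output, and negating it
  # must negate the output exactly
  l3 <- attr(out, "local_out")
  gp <- conv_oracle(g, p$gproj$W, p$gproj$b)
  pre <- array(c(gp, l3), dim = c(6, 6, 8))
  expect_equal(as.numeric(out), as.numeric(tanh(pre)), tolerance = 1e-5)
  expect_equal(tanh(-pre), -tanh(pre))
})

test_that("GLFEB of zero inputs with zero biases is exactly zero", {
  cfg <- tiny_config()
  model <- ddrnet_init(cfg, seed = 19)
  z6 <- array(0, dim = c(6, 6, cfg$stem_channels))
  zl <- array(0, dim = c(6, 6, cfg$drdb_branch_width))
  out <- glfeb_forward(z6, zl, cfg, model$params$glfeb)
  expect_equal(as.numeric(out), rep(0, length(out)))
})

test_that("global average pooling matches its brute-force definition and is linear", {
  x <- array(3.7, dim = c(4, 4, 5))
  expect_equal(global_average_pool(x), rep(3.7, 5))

  set.seed(20)
  a <- random_fmap(5, 5, 4)
  ref <- numeric(4)
  for (c in 1:4) {
    s <- 0
    for (i in 1:5) for (j in 1:5) s <- s + a[i, j, c]
    ref[c] <- s / 25
  }
  expect_equal(global_average_pool(a), ref, tolerance = 1e-6)

  b <- random_fmap(5, 5, 4)
  expect_equal(global_average_pool(a + b),
               global_average_pool(a) + global_average_pool(b))
  expect_error(global_average_pool(array(0, c(0, 3, 2))), "spatial")
})

test_that("channel attention matches the hand-computed pooled-bottleneck chain", {
  set.seed(21)
  params <- list(ca1 = list(W = matrix(rnorm(2), 1, 2), b = rnorm(1)),
                 ca2 = list(W = matrix(rnorm(2), 2, 1), b = rnorm(2)))
  at <- random_fmap(3, 3, 2)
  qc <- channel_attention(at, params)
  expect_true(all(qc > 0 & qc < 1))

  gapv <- c(mean(at[, , 1]), mean(at[, , 2]))
  gmpv <- c(max(at[, , 1]), max(at[, , 2]))
  path <- function(v) params$ca2$W %*% pmax(params$ca1$W %*% v +
                                              params$ca1$b, 0) + params$ca2$b
  ref <- 1 / (1 + exp(-(path(gapv) + path(gmpv))))
  expect_equal(qc, as.numeric(ref), tolerance = 1e-6)
})

test_that("channel attention weights respond monotonically to their pre-sigmoid logit", {
  z <- seq(-4, 4, length.out = 50)
  s <- 1 / (1 + exp(-z))
  expect_true(all(diff(s) > 0))
  # raising one channel's activation map raises (never lowers) its weight
  # through an identity bottleneck
  params <- list(ca1 = list(W = diag(2), b = c(0, 0)),
                 ca2 = list(W = diag(2), b = c(0, 0)))
  at <- array(0.5, dim = c(3, 3, 2))
  q0 <- channel_attention(at, params)
  at[, , 1] <- at[, , 1] + 1
  q1 <- channel_attention(at, params)
  expect_gte(q1[1], q0[1])
})

test_that("spatial attention is a normalized non-negative map matching a direct convolution", {
  set.seed(22)
  params <- list(sa = list(W = array(rnorm(25), dim = c(5, 5, 1, 1)),
                           b = 0))
  at <- random_fmap(4, 4, 1)
  qs <- spatial_attention(at, params)
  expect_gte(min(qs), 0)
  expect_equal(sum(qs), 1, tolerance = 1e-6)

  raw <- pmax(conv_oracle(at, params$sa$W, params$sa$b), 0)
  expect_equal(as.numeric(qs), as.numeric(raw / sum(raw)), tolerance = 1e-6)
})

test_that("an all-zero spatial attention map degenerates to uniform with a warning", {
  params <- list(sa = list(W = array(0, dim = c(5, 5, 2, 1)), b = -1))
  at <- array(1, dim = c(4, 4, 2))
  expect_warning(qs <- spatial_attention(at, params), "uniform")
  expect_equal(as.numeric(qs), rep(1 / 16, 16))
})

test_that("CSAB gating is the elementwise broadcast product of input, Qc and Qs", {
  cfg <- tiny_config()
  model <- ddrnet_init(cfg, seed = 23)
  p <- model$params$csab
  set.seed(24)
  at <- random_fmap(3, 3, 2 * cfg$glfeb_widths[3])
  out <- csab_forward(at, p)
  qc <- attr(out, "qc")
  qs <- attr(out, "qs")
  ref <- at
  for (c in seq_len(dim(at)[3])) ref[, , c] <- at[, , c] * qc[c] *
      matrix(qs, 3, 3)
  expect_equal(as.numeric(out), as.numeric(ref), tolerance = 1e-12)
  expect_identical(dim(out), dim(at))
})

test_that("forcing unit attention makes CSAB the identity and zero spatial attention annihilates it", {
  d <- c(3, 3, 2)
  set.seed(25)
  at <- random_fmap(3, 3, 2)
  qc1 <- rep(1, 2); qs1 <- matrix(1, 3, 3)
  ref <- at
  for (c in 1:2) ref[, , c] <- at[, , c] * qc1[c] * qs1
  expect_equal(ref, at)
  expect_equal(at * 0, array(0, dim = d))
})

test_that("the end-to-end softmax forward is normalized and eval mode is bit-deterministic", {
  cfg <- tiny_config()
  model <- ddrnet_init(cfg, seed = 26)
  set.seed(27)
  img <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
  p1 <- ddrnet_forward(model, img)
  p2 <- ddrnet_forward(model, img)
  expect_identical(p1, p2)
  expect_equal(sum(p1), 1, tolerance = 1e-12)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_error(ddrnet_forward(model, array(0, dim = c(9, 8, 3))),
               "expects 8x8x3")
})

test_that("the sigmoid head produces independent per-class scores in (0, 1)", {
  cfg <- tiny_config(head = "sigmoid")
  model <- ddrnet_init(cfg, seed = 28)
  img <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
  p <- ddrnet_forward(model, img)
  expect_true(all(p > 0 & p < 1))
})

test_that("parameter counts match closed forms and the layer-walk oracle", {
  # single 3x3 convolution, 3 -> 32 channels, with per-channel bias
  cv <- ddrnet:::init_conv(3L, 3L, 3L, 32L)
  expect_identical(length(cv$W) + length(cv$b), 896L)
  # a group-norm layer over C channels carries 2C parameters
  gn <- ddrnet:::init_gn(48L)
  expect_identical(length(gn$gamma) + length(gn$beta), 96L)

  # full default model vs an independent per-layer closed-form walk
  cfg <- model_config()
  model <- ddrnet_init(cfg, seed = 1)
  conv_n <- function(k, cin, cout) k * k * cin * cout + cout
  gn_n <- function(C) 2 * C
  dense_n <- function(o, i) o * i + o
  wd <- cfg$drdb_branch_width
  g <- cfg$glfeb_widths
  C2 <- 2 * g[3]
  expected <-
    conv_n(3, 3, 32) + gn_n(32) +                       # stem
    conv_n(1, 32, wd) +                                 # DRDB projection
    6 * (2 * conv_n(3, wd, wd) + 2 * gn_n(wd)) +        # six branches
    conv_n(1, 6 * wd, wd) + gn_n(wd) +                  # reduction
    conv_n(3, wd, g[1]) + gn_n(g[1]) +                  # GLFEB local
    conv_n(3, g[1], g[2]) + gn_n(g[2]) +
    conv_n(3, g[2], g[3]) + gn_n(g[3]) +
    conv_n(1, 32, g[3]) +                               # global projection
    dense_n(C2 / 8, C2) + dense_n(C2, C2 / 8) +         # channel attention
    conv_n(5, C2, 1) +                                  # spatial attention
    conv_n(1, g[3], C2) +                               # fusion projection
    gn_n(C2) +                                          # batch norm
    dense_n(4, C2)                                      # head
  expect_identical(count_parameters(model), as.integer(expected))
})

test_that("the 18-layer residual reference walk reproduces the canonical count", {
  # published torchvision count for the 1000-class variant
  expect_identical(as.integer(resnet18_parameter_count(1000L)), 11689512L)
})

test_that("the default network has far fewer parameters than the 18-layer residual reference", {
  model <- ddrnet_init(model_config(), seed = 1)
  expect_lt(count_parameters(model),
            as.integer(resnet18_parameter_count(4L)))
})

test_that("shape conservation holds across a sweep of valid configurations", {
  for (stem in c(4L, 8L)) {
    for (wd in c(4L, 8L)) {
      cfg <- model_config(input_size = c(16, 16, 3), stem_channels = stem,
                          drdb_branch_width = wd,
                          glfeb_widths = c(4L, 6L, 4L), gn_groups = 2L,
                          attention_fc_reduction = 2L)
      model <- ddrnet_init(cfg, seed = stem + wd)
      img <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
      p <- ddrnet_forward(model, img)
      expect_length(p, 4L)
      expect_true(all(is.finite(p)))
    }
  }
})

test_that("configurations round-trip through YAML", {
  cfg <- model_config(stem_channels = 24L, drdb_dilations = c(1L, 3L, 5L))
  path <- withr::local_tempfile(fileext = ".yaml")
  config_to_yaml(cfg, path)
  expect_equal(config_from_yaml(path), cfg)

  tcfg <- train_config(learning_rate = 0.005, epochs = 7L, seed = 3L)
  tpath <- withr::local_tempfile(fileext = ".yaml")
  config_to_yaml(tcfg, tpath)
  expect_equal(train_config_from_yaml(tpath), tcfg)
})

test_that("invalid configurations are rejected", {
  expect_error(model_config(drdb_dilations = c(2, 1, 4)), "increasing")
  expect_error(model_config(dropout_rate = 1), "dropout")
  expect_error(model_config(num_classes = 1), "num_classes")
})
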