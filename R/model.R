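# Network assembly: parameter initialization, the end-to-end forward pass
# with caches, and the hand-derived backward pass. Parameters live in a
# nested list mirroring the block structure; gradients come back in a list
# of identical shape.

init_conv <- function(kh, kw, cin, cout) {
  lim <- sqrt(6 / (kh * kw * cin))
  list(W = array(runif(kh * kw * cin * cout, -lim, lim),
                 dim = c(kh, kw, cin, cout)),
       b = numeric(cout))
}

init_gn <- function(C) list(gamma = rep(1, C), beta = rep(0, C))

init_dense <- function(nout, nin) {
  lim <- sqrt(6 / nin)
  list(W = matrix(runif(nout * nin, -lim, lim), nout, nin), b = numeric(nout))
}

init_branch <- function(width, dilation) {
  list(conv1 = init_conv(3L, 3L, width, width),
       gn1 = init_gn(width),
       conv2 = init_conv(3L, 3L, width, width),
       gn2 = init_gn(width),
       dilation = as.integer(dilation))
}

# channel widths of the intermediate features implied by a config
config_widths <- function(cfg) {
  r_ch <- if (cfg$use_drdb) cfg$drdb_branch_width else cfg$stem_channels
  g3 <- cfg$glfeb_widths[3L]
  o_ch <- if (cfg$use_glfeb) 2L * g3 else r_ch
  list(stem = cfg$stem_channels, r = r_ch, g3 = g3, o = o_ch, final = o_ch)
}

#' Instantiate a DDRNet model
#'
#' Convolution weights use He-uniform initialization, normalization layers
#' start at unit gain / zero shift. The dilation pattern of the six residual
#' branches is fixed at (1, 1, 1, d1, d2, d3): plain branches at positions
#' 1, 3, 5 and dilated branches at 2, 4, 6.
#'
#' @param cfg a [model_config()].
#' @param seed optional integer seed for reproducible initialization.
#' @return An object of class `ddrnet_model`: a list with elements `config`,
#'   `params` (nested parameter list) and `state` (batch-norm running
#'   statistics).
#' @export
ddrnet_init <- function(cfg = model_config(), seed = NULL) {
  validate_model_config(cfg)
  if (!is.null(seed)) set.seed(seed)
  w <- config_widths(cfg)
  p <- list(stem = list(conv = init_conv(3L, 3L, cfg$input_size[3L],
                                         cfg$stem_channels),
                        gn = init_gn(cfg$stem_channels)))
  if (cfg$use_drdb) {
    dil6 <- branch_dilations(cfg)
    wd <- cfg$drdb_branch_width
    p$drdb <- lapply(seq_len(cfg$drdb_depth), function(s) {
      cin <- if (s == 1L) cfg$stem_channels else wd
      list(proj = init_conv(1L, 1L, cin, wd),
           branches = lapply(dil6, function(d) init_branch(wd, d)),
           fuse = init_conv(1L, 1L, 6L * wd, wd),
           fuse_gn = init_gn(wd))
    })
  }
  if (cfg$use_glfeb) {
    g <- cfg$glfeb_widths
    p$glfeb <- list(
      l1 = list(conv = init_conv(3L, 3L, w$r, g[1L]), gn = init_gn(g[1L])),
      l2 = list(conv = init_conv(3L, 3L, g[1L], g[2L]), gn = init_gn(g[2L])),
      l3 = list(conv = init_conv(3L, 3L, g[2L], g[3L]), gn = init_gn(g[3L])),
      gproj = init_conv(1L, 1L, cfg$stem_channels, g[3L]))
  }
  if (cfg$use_csab) {
    C <- w$o
    mid <- max(1L, C %/% cfg$attention_fc_reduction)
    p$csab <- list(ca1 = init_dense(mid, C),
                   ca2 = init_dense(C, mid),
                   sa = init_conv(cfg$csab_kernel, cfg$csab_kernel, C, 1L))
  }
  if (cfg$use_glfeb) p$fuse <- list(proj = init_conv(1L, 1L, w$g3, w$o))
  p$post <- list(bn = init_gn(w$final))
  p$head <- list(fc = init_dense(cfg$num_classes, w$final))

  structure(list(config = cfg, params = p,
                 state = list(bn_mean = rep(0, w$final),
                              bn_var = rep(1, w$final))),
            class = "ddrnet_model")
}

branch_dilations <- function(cfg) {
  d <- cfg$drdb_dilations
  c(1L, d[1L], 1L, d[2L], 1L, d[3L])
}

#' @export
print.ddrnet_model <- function(x, ...) {
  cat("DDRNet model,", format(count_parameters(x), big.mark = ","),
      "trainable parameters\n")
  print(x$config)
  invisible(x)
}

# --- residual branch --------------------------------------------------------

branch_fwd <- function(x, p, groups, dilation = p$dilation) {
  C <- dim(x)[3L]
  G <- gn_groups_for(C, groups)
  c1 <- conv_fwd(x, p$conv1$W, p$conv1$b, dilation)
  n1 <- gn_fwd(c1$y, G, p$gn1$gamma, p$gn1$beta)
  r1 <- relu_fwd(n1$y)
  c2 <- conv_fwd(r1$y, p$conv2$W, p$conv2$b, dilation)
  n2 <- gn_fwd(c2$y, G, p$gn2$gamma, p$gn2$beta)
  list(y = x + n2$y, cache = list(c1 = c1$cache, n1 = n1$cache, r1 = r1$cache,
                                  c2 = c2$cache, n2 = n2$cache))
}

branch_bwd <- function(cache, dy) {
  n2 <- gn_bwd(cache$n2, dy)
  c2 <- conv_bwd(cache$c2, n2$dx)
  dr1 <- relu_bwd(cache$r1, c2$dx)
  n1 <- gn_bwd(cache$n1, dr1)
  c1 <- conv_bwd(cache$c1, n1$dx)
  list(dx = dy + c1$dx,
       grads = list(conv1 = list(W = c1$dW, b = c1$db),
                    gn1 = list(gamma = n1$dgamma, beta = n1$dbeta),
                    conv2 = list(W = c2$dW, b = c2$db),
                    gn2 = list(gamma = n2$dgamma, beta = n2$dbeta)))
}

# --- channel concatenation --------------------------------------------------

cat_channels <- function(lst) {
  d <- dim(lst[[1L]])
  cs <- vapply(lst, function(a) dim(a)[3L], 1L)
  out <- array(0, dim = c(d[1L], d[2L], sum(cs), d[4L]))
  at <- 0L
  for (a in lst) {
    ca <- dim(a)[3L]
    out[, , at + seq_len(ca), ] <- a
    at <- at + ca
  }
  out
}

split_channels <- function(x, sizes) {
  at <- 0L
  lapply(sizes, function(ca) {
    sl <- x[, , at + seq_len(ca), , drop = FALSE]
    at <<- at + ca
    sl
  })
}

# --- stages -----------------------------------------------------------------

stem_fwd <- function(x, p, groups) {
  cv <- conv_fwd(x, p$conv$W, p$conv$b, 1L)
  pl <- pool_fwd(cv$y)
  G <- gn_groups_for(dim(pl$y)[3L], groups)
  gn <- gn_fwd(pl$y, G, p$gn$gamma, p$gn$beta)
  rl <- relu_fwd(gn$y)
  list(y = rl$y, cache = list(cv = cv$cache, pl = pl$cache, gn = gn$cache,
                              rl = rl$cache))
}

stem_bwd <- function(cache, dy) {
  dgn <- relu_bwd(cache$rl, dy)
  g <- gn_bwd(cache$gn, dgn)
  dpl <- pool_bwd(cache$pl, g$dx)
  cv <- conv_bwd(cache$cv, dpl)
  list(dx = cv$dx,
       grads = list(conv = list(W = cv$dW, b = cv$db),
                    gn = list(gamma = g$dgamma, beta = g$dbeta)))
}

drdb_stage_fwd <- function(x, p, groups) {
  pj <- conv_fwd(x, p$proj$W, p$proj$b, 1L)
  brs <- lapply(p$branches, function(bp) branch_fwd(pj$y, bp, groups))
  cat <- cat_channels(lapply(brs, `[[`, "y"))
  fu <- conv_fwd(cat, p$fuse$W, p$fuse$b, 1L)
  G <- gn_groups_for(dim(fu$y)[3L], groups)
  fg <- gn_fwd(fu$y, G, p$fuse_gn$gamma, p$fuse_gn$beta)
  rl <- relu_fwd(fg$y)
  list(y = rl$y, concat_width = dim(cat)[3L],
       cache = list(pj = pj$cache, brs = lapply(brs, `[[`, "cache"),
                    width = dim(pj$y)[3L], fu = fu$cache, fg = fg$cache,
                    rl = rl$cache))
}

drdb_stage_bwd <- function(cache, dy) {
  dfg <- relu_bwd(cache$rl, dy)
  fg <- gn_bwd(cache$fg, dfg)
  fu <- conv_bwd(cache$fu, fg$dx)
  parts <- split_channels(fu$dx, rep(cache$width, 6L))
  dproj_y <- 0
  br_grads <- vector("list", 6L)
  for (k in seq_len(6L)) {
    bg <- branch_bwd(cache$brs[[k]], parts[[k]])
    dproj_y <- dproj_y + bg$dx
    br_grads[[k]] <- bg$grads
  }
  pj <- conv_bwd(cache$pj, dproj_y)
  list(dx = pj$dx,
       grads = list(proj = list(W = pj$dW, b = pj$db),
                    branches = br_grads,
                    fuse = list(W = fu$dW, b = fu$db),
                    fuse_gn = list(gamma = fg$dgamma, beta = fg$dbeta)))
}

conv_gn_relu_fwd <- function(x, p, groups) {
  cv <- conv_fwd(x, p$conv$W, p$conv$b, 1L)
  G <- gn_groups_for(dim(cv$y)[3L], groups)
  gn <- gn_fwd(cv$y, G, p$gn$gamma, p$gn$beta)
  rl <- relu_fwd(gn$y)
  list(y = rl$y, cache = list(cv = cv$cache, gn = gn$cache, rl = rl$cache))
}

conv_gn_relu_bwd <- function(cache, dy) {
  dgn <- relu_bwd(cache$rl, dy)
  g <- gn_bwd(cache$gn, dgn)
  cv <- conv_bwd(cache$cv, g$dx)
  list(dx = cv$dx,
       grads = list(conv = list(W = cv$dW, b = cv$db),
                    gn = list(gamma = g$dgamma, beta = g$dbeta)))
}

glfeb_stage_fwd <- function(global, local, p, groups) {
  l1 <- conv_gn_relu_fwd(local, p$l1, groups)
  l2 <- conv_gn_relu_fwd(l1$y, p$l2, groups)
  l3 <- conv_gn_relu_fwd(l2$y, p$l3, groups)
  dl <- dim(l3$y)
  rz <- resize_fwd(global, dl[1L], dl[2L])
  gp <- conv_fwd(rz$y, p$gproj$W, p$gproj$b, 1L)
  cat <- cat_channels(list(gp$y, l3$y))
  th <- tanh_fwd(cat)
  list(y = th$y, local_out = l3$y,
       cache = list(l1 = l1$cache, l2 = l2$cache, l3 = l3$cache,
                    rz = rz$cache, gp = gp$cache, th = th$cache,
                    gch = dim(gp$y)[3L], lch = dl[3L]))
}

# dl3_extra: gradient reaching the local conv output through the fusion path
glfeb_stage_bwd <- function(cache, dy, dl3_extra = NULL) {
  dcat <- tanh_bwd(cache$th, dy)
  parts <- split_channels(dcat, c(cache$gch, cache$lch))
  gp <- conv_bwd(cache$gp, parts[[1L]])
  dglobal <- resize_bwd(cache$rz, gp$dx)
  dl3 <- parts[[2L]]
  if (!is.null(dl3_extra)) dl3 <- dl3 + dl3_extra
  l3 <- conv_gn_relu_bwd(cache$l3, dl3)
  l2 <- conv_gn_relu_bwd(cache$l2, l3$dx)
  l1 <- conv_gn_relu_bwd(cache$l1, l2$dx)
  list(dlocal = l1$dx, dglobal = dglobal,
       grads = list(l1 = l1$grads, l2 = l2$grads, l3 = l3$grads,
                    gproj = list(W = gp$dW, b = gp$db)))
}

# --- channel + spatial attention --------------------------------------------

ca_fwd <- function(x, p) {
  ga <- gap_fwd(x)
  gm <- gmp_fwd(x)
  d1a <- dense_fwd(ga$y, p$ca1$W, p$ca1$b); r1a <- relu_fwd(d1a$y)
  d2a <- dense_fwd(r1a$y, p$ca2$W, p$ca2$b)
  d1m <- dense_fwd(gm$y, p$ca1$W, p$ca1$b); r1m <- relu_fwd(d1m$y)
  d2m <- dense_fwd(r1m$y, p$ca2$W, p$ca2$b)
  qc <- sigmoid(d2a$y + d2m$y)
  list(qc = qc, cache = list(ga = ga$cache, gm = gm$cache,
                             d1a = d1a$cache, r1a = r1a$cache, d2a = d2a$cache,
                             d1m = d1m$cache, r1m = r1m$cache, d2m = d2m$cache,
                             qc = qc))
}

ca_bwd <- function(cache, dqc) {
  dz <- dqc * cache$qc * (1 - cache$qc)
  a2 <- dense_bwd(cache$d2a, dz)
  a1 <- dense_bwd(cache$d1a, relu_bwd(cache$r1a, a2$dx))
  m2 <- dense_bwd(cache$d2m, dz)
  m1 <- dense_bwd(cache$d1m, relu_bwd(cache$r1m, m2$dx))
  dx <- gap_bwd(cache$ga, a1$dx) + gmp_bwd(cache$gm, m1$dx)
  list(dx = dx,
       grads = list(ca1 = list(W = a1$dW + m1$dW, b = a1$db + m1$db),
                    ca2 = list(W = a2$dW + m2$dW, b = a2$db + m2$db)))
}

sa_fwd <- function(x, p, warn_degenerate = TRUE) {
  cv <- conv_fwd(x, p$sa$W, p$sa$b, 1L)
  rl <- relu_fwd(cv$y)
  d <- dim(rl$y)                       # (H, W, 1, N)
  hw <- d[1L] * d[2L]
  q <- rl$y
  dim(q) <- c(hw, d[4L])
  s <- colSums(q)
  degen <- s <= 0
  if (any(degen) && warn_degenerate)
    warning("spatial attention map is all zero; using a uniform map")
  qs <- q
  for (n in seq_len(d[4L]))
    qs[, n] <- if (degen[n]) 1 / hw else q[, n] / s[n]
  list(qs = qs, dims = d,
       cache = list(cv = cv$cache, rl = rl$cache, qs = qs, s = s,
                    degen = degen, dims = d))
}

sa_bwd <- function(cache, dqs) {
  d <- cache$dims
  hw <- d[1L] * d[2L]
  dq <- dqs
  for (n in seq_len(d[4L])) {
    if (cache$degen[n]) {
      dq[, n] <- 0
    } else {
      dq[, n] <- (dqs[, n] - sum(dqs[, n] * cache$qs[, n])) / cache$s[n]
    }
  }
  dim(dq) <- d
  drl <- relu_bwd(cache$rl, dq)
  cv <- conv_bwd(cache$cv, drl)
  list(dx = cv$dx, grads = list(sa = list(W = cv$dW, b = cv$db)))
}

csab_stage_fwd <- function(x, p, warn_degenerate = TRUE) {
  d <- dim(x)
  hw <- d[1L] * d[2L]; C <- d[3L]; N <- d[4L]
  ca <- ca_fwd(x, p)
  sa <- sa_fwd(x, p, warn_degenerate)
  xm <- x
  dim(xm) <- c(hw, C * N)
  qs_big <- sa$qs[, rep(seq_len(N), each = C), drop = FALSE]
  y <- sweep(xm, 2L, as.numeric(ca$qc), `*`) * qs_big
  dim(y) <- d
  list(y = y, qc = ca$qc, qs = matrix(sa$qs, hw, N),
       cache = list(ca = ca$cache, sa = sa$cache, x = x, qc = ca$qc,
                    qs_big = qs_big, dims = d))
}

csab_stage_bwd <- function(cache, dy) {
  d <- cache$dims
  hw <- d[1L] * d[2L]; C <- d[3L]; N <- d[4L]
  dym <- dy; dim(dym) <- c(hw, C * N)
  xm <- cache$x; dim(xm) <- c(hw, C * N)
  qcv <- as.numeric(cache$qc)

  dx1 <- sweep(dym, 2L, qcv, `*`) * cache$qs_big
  dqc <- matrix(.colSums(dym * xm * cache$qs_big, hw, C * N), C, N)
  t1 <- sweep(dym * xm, 2L, qcv, `*`)           # (hw, C*N)
  dim(t1) <- c(hw, C, N)
  t1 <- aperm(t1, c(1L, 3L, 2L))
  dim(t1) <- c(hw * N, C)
  dqs <- matrix(.rowSums(t1, hw * N, C), hw, N)

  ca <- ca_bwd(cache$ca, dqc)
  sa <- sa_bwd(cache$sa, dqs)
  dim(dx1) <- d
  list(dx = dx1 + ca$dx + sa$dx,
       grads = c(ca$grads, sa$grads))
}

# --- full network -----------------------------------------------------------

net_fwd <- function(model, x, mode = c("eval", "train"), keep_acts = FALSE) {
  mode <- match.arg(mode)
  cfg <- model$config
  p <- model$params
  x <- as_batch(x)
  din <- dim(x)
  if (din[3L] != cfg$input_size[3L] ||
      din[1L] != cfg$input_size[1L] || din[2L] != cfg$input_size[2L])
    stop(sprintf("input is %dx%dx%d but the model expects %dx%dx%d",
                 din[1L], din[2L], din[3L], cfg$input_size[1L],
                 cfg$input_size[2L], cfg$input_size[3L]))
  acts <- if (keep_acts) list() else NULL

  st <- stem_fwd(x, p$stem, cfg$gn_groups)
  s <- st$y
  if (keep_acts) acts$stem <- s

  r <- s
  drdb_caches <- NULL
  if (cfg$use_drdb) {
    drdb_caches <- vector("list", cfg$drdb_depth)
    for (k in seq_len(cfg$drdb_depth)) {
      stg <- drdb_stage_fwd(r, p$drdb[[k]], cfg$gn_groups)
      drdb_caches[[k]] <- stg$cache
      r <- stg$y
    }
    if (keep_acts) acts$drdb <- r
  }

  gl <- NULL
  if (cfg$use_glfeb) {
    gl <- glfeb_stage_fwd(s, r, p$glfeb, cfg$gn_groups)
    o <- gl$y
    if (keep_acts) acts$glfeb <- o
  } else o <- r

  cs <- NULL
  if (cfg$use_csab) {
    cs <- csab_stage_fwd(o, p$csab, warn_degenerate = FALSE)
    a <- cs$y
    if (keep_acts) acts$csab <- a
  } else a <- o

  fl_cache <- NULL
  if (cfg$use_glfeb) {
    fl <- conv_fwd(gl$local_out, p$fuse$proj$W, p$fuse$proj$b, 1L)
    fl_cache <- fl$cache
    f <- a + fl$y
  } else f <- a
  if (keep_acts) acts$fusion <- f

  bn <- bn_fwd(f, p$post$bn$gamma, p$post$bn$beta,
               model$state$bn_mean, model$state$bn_var, mode)
  dp <- dropout_fwd(bn$y, cfg$dropout_rate, mode)
  gp <- gap_fwd(dp$y)
  hd <- dense_fwd(gp$y, p$head$fc$W, p$head$fc$b)
  logits <- hd$y

  probs <- if (cfg$head == "softmax") softmax_cols(logits) else sigmoid(logits)

  list(logits = logits, probs = probs, acts = acts,
       state = list(bn_mean = bn$run_mean, bn_var = bn$run_var),
       caches = list(st = st$cache, drdb = drdb_caches, gl = gl,
                     cs = cs, fl = fl_cache, bn = bn$cache, dp = dp$cache,
                     gp = gp$cache, hd = hd$cache,
                     dims = din, mode = mode))
}

# dlogits: (K, N). taps: names among stem/drdb/glfeb/csab/fusion for which
# the gradient w.r.t. that activation is returned.
net_bwd <- function(model, caches, dlogits, taps = character()) {
  cfg <- model$config
  tap_out <- list()

  hd <- dense_bwd(caches$hd, dlogits)
  dgp <- gap_bwd(caches$gp, hd$dx)
  ddp <- dropout_bwd(caches$dp, dgp)
  if (caches$mode == "train") {
    bn <- bn_bwd(caches$bn, ddp)
    df <- bn$dx
    bn_g <- list(gamma = bn$dgamma, beta = bn$dbeta)
  } else {
    # eval-mode pass (Grad-CAM): running stats are constants
    scale <- model$params$post$bn$gamma /
      sqrt(model$state$bn_var + 1e-5)
    d <- dim(ddp)
    df <- ddp
    dim(df) <- c(d[1L] * d[2L], d[3L] * d[4L])
    df <- sweep(df, 2L, rep(scale, times = d[4L]), `*`)
    dim(df) <- d
    bn_g <- list(gamma = numeric(length(scale)),
                 beta = numeric(length(scale)))
  }
  if ("fusion" %in% taps) tap_out$fusion <- df

  grads <- list()
  dl3_extra <- NULL
  da <- df
  if (cfg$use_glfeb) {
    fl <- conv_bwd(caches$fl, df)
    grads$fuse <- list(proj = list(W = fl$dW, b = fl$db))
    dl3_extra <- fl$dx
  }
  if ("csab" %in% taps) tap_out$csab <- da

  if (cfg$use_csab) {
    cs <- csab_stage_bwd(caches$cs$cache, da)
    grads$csab <- cs$grads
    do <- cs$dx
  } else do <- da
  if ("glfeb" %in% taps) tap_out$glfeb <- do

  ds_extra <- NULL
  if (cfg$use_glfeb) {
    gl <- glfeb_stage_bwd(caches$gl$cache, do, dl3_extra)
    grads$glfeb <- gl$grads
    dr <- gl$dlocal
    ds_extra <- gl$dglobal
  } else dr <- do
  if ("drdb" %in% taps) tap_out$drdb <- dr

  if (cfg$use_drdb) {
    grads$drdb <- vector("list", cfg$drdb_depth)
    for (k in rev(seq_len(cfg$drdb_depth))) {
      stg <- drdb_stage_bwd(caches$drdb[[k]], dr)
      grads$drdb[[k]] <- stg$grads
      dr <- stg$dx
    }
    ds <- dr
  } else ds <- dr
  if (!is.null(ds_extra)) ds <- ds + ds_extra
  if ("stem" %in% taps) tap_out$stem <- ds

  st <- stem_bwd(caches$st, ds)
  grads$stem <- st$grads
  grads$post <- list(bn = bn_g)
  grads$head <- list(fc = list(W = hd$dW, b = hd$db))
  list(grads = grads, taps = tap_out, dx = NULL)
}

# --- parameter accounting ---------------------------------------------------

flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    v <- p[[nm]]
    key <- if (prefix == "") nm else paste(prefix, nm, sep = ".")
    if (is.numeric(v)) {
      if (nm != "dilation") out[[key]] <- v
    } else if (is.list(v)) {
      if (is.null(names(v))) {
        for (i in seq_along(v))
          out <- c(out, flatten_params(v[[i]], paste0(key, i)))
      } else out <- c(out, flatten_params(v, key))
    }
  }
  out
}

#' Count trainable parameters
#'
#' @param model a `ddrnet_model`, or a nested parameter list.
#' @return Integer: the exact number of trainable scalars.
#' @export
count_parameters <- function(model) {
  p <- if (inherits(model, "ddrnet_model")) model$params else model
  sum(vapply(flatten_params(p), length, integer(1L)))
}

#' Parameter count of a standard 18-layer residual reference network
#'
#' Walks the canonical 18-layer residual architecture (7x7/64 stem with
#' batch norm, four stages of two basic blocks at widths 64/128/256/512
#' with 1x1 projection shortcuts on stage transitions, global pooling and a
#' dense head; convolutions unbiased as usual when followed by batch norm)
#' and sums closed-form per-layer counts. Used as the reference for the
#' parameter-economy claim: the default DDRNet has far fewer trainable
#' parameters at the same input/output sizes.
#'
#' @param num_classes classes in the dense head (default 4).
#' @param in_channels input image channels (default 3).
#' @return Integer count, with a per-layer breakdown in attribute `"layers"`.
#' @export
resnet18_parameter_count <- function(num_classes = 4L, in_channels = 3L) {
  rows <- list()
  add <- function(name, n) rows[[length(rows) + 1L]] <<- list(name = name, n = n)
  conv <- function(k, cin, cout) k * k * cin * cout   # no bias before BN
  bnp <- function(C) 2L * C

  add("conv1 7x7", conv(7L, in_channels, 64L))
  add("bn1", bnp(64L))
  widths <- c(64L, 128L, 256L, 512L)
  cin <- 64L
  for (s in seq_along(widths)) {
    w <- widths[s]
    for (b in 1:2) {
      down <- b == 1L && w != cin
      add(sprintf("stage%d.block%d.conv1", s, b), conv(3L, cin, w))
      add(sprintf("stage%d.block%d.bn1", s, b), bnp(w))
      add(sprintf("stage%d.block%d.conv2", s, b), conv(3L, w, w))
      add(sprintf("stage%d.block%d.bn2", s, b), bnp(w))
      if (down) {
        add(sprintf("stage%d.block%d.down.conv", s, b), conv(1L, cin, w))
        add(sprintf("stage%d.block%d.down.bn", s, b), bnp(w))
      }
      cin <- w
    }
  }
  add("fc", 512L * num_classes + num_classes)
  total <- sum(vapply(rows, `[[`, numeric(1L), "n"))
  structure(total,
            layers = data.frame(
              name = vapply(rows, `[[`, character(1L), "name"),
              params = vapply(rows, `[[`, numeric(1L), "n")))
}
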