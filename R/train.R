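# Training loop (Adam, constant learning rate, minibatches), evaluation and
# prediction. Seeded end-to-end in deterministic mode: initialization,
# shuffling and dropout all draw from R's RNG.

# recursive Adam step over the nested parameter list
adam_init_like <- function(p) {
  if (is.numeric(p)) return(p * 0)
  lapply(p, adam_init_like)
}

adam_step <- function(p, g, m, v, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  if (is.numeric(p)) {
    if (is.null(g)) return(list(p = p, m = m, v = v))
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    return(list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v))
  }
  nms <- names(p)
  for (i in seq_along(p)) {
    nm <- if (!is.null(nms)) nms[i] else NULL
    if (identical(nm, "dilation")) next
    gi <- if (!is.null(nm) && !is.null(g)) g[[nm]] else g[[i]]
    r <- adam_step(p[[i]], gi, m[[i]], v[[i]], lr, t, beta1, beta2, eps)
    p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
  }
  list(p = p, m = m, v = v)
}

loss_and_grad <- function(model, logits, onehot) {
  if (model$config$head == "softmax") softmax_ce(logits, onehot) else
    sigmoid_bce(logits, onehot)
}

onehot_matrix <- function(labels, classes) {
  y <- matrix(0, length(classes), length(labels))
  y[cbind(match(as.character(labels), classes), seq_along(labels))] <- 1
  y
}

#' Train a DDRNet model
#'
#' Minibatch Adam with a constant learning rate. Per epoch the training
#' split is reshuffled, and training loss/accuracy are accumulated over the
#' minibatches; validation metrics use the `"val"` split when present and
#' fall back to an eval-mode pass over the training split otherwise. The
#' parameters with the best validation accuracy (ties broken by lower
#' validation loss) are kept. A non-finite loss aborts with a diagnostic
#' naming the epoch and iteration.
#'
#' @param model a [ddrnet_init()] model.
#' @param data a [labeled_image_set()] with a `"train"` split (any set
#'   without split tags is treated as all-train).
#' @param cfg a [train_config()].
#' @param verbose print one line per epoch (default `FALSE`).
#' @param log_file optional path; per-epoch log lines are appended there in
#'   addition to the console.
#' @return List with `model` (best-validation weights) and `history` (data
#'   frame with per-epoch train/val loss and accuracy and the iteration
#'   counter).
#' @export
train_model <- function(model, data, cfg = train_config(),
                        verbose = FALSE, log_file = NULL) {
  stopifnot(inherits(model, "ddrnet_model"),
            inherits(data, "cell_image_set"))
  classes <- class_names_for(model$config$num_classes)
  if (!all(levels(droplevels(data$labels)) %in% classes))
    stop("data classes do not match the model's classes")

  if (cfg$deterministic_mode) set.seed(cfg$seed)

  idx_train <- if (is.null(data$split)) seq_along(data$images) else
    which(data$split == "train")
  if (length(idx_train) == 0L) stop("data has no training split")
  idx_val <- if (is.null(data$split)) integer() else
    which(data$split == "val")
  if (length(idx_val) == 0L && cfg$val_frac > 0) {
    n_val <- max(1L, round(cfg$val_frac * length(idx_train)))
    idx_val <- sample(idx_train, n_val)
    idx_train <- setdiff(idx_train, idx_val)
  }

  insz <- model$config$input_size
  # pre-resize once; at reduced input sizes this is the cheap part
  pre <- lapply(data$images, function(im)
    if (dim(im)[1L] != insz[1L] || dim(im)[2L] != insz[2L])
      resize_bilinear(im, insz[1L], insz[2L]) else im)
  lab <- as.character(data$labels)

  m_state <- adam_init_like(model$params)
  v_state <- adam_init_like(model$params)
  t_step <- 0L
  hist <- vector("list", cfg$epochs)
  best <- list(acc = -Inf, loss = Inf, params = model$params,
               state = model$state)

  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(idx_train)
    n_batches <- ceiling(length(ord) / cfg$batch_size)
    tot_loss <- 0; tot_correct <- 0L
    for (b in seq_len(n_batches)) {
      take <- ord[((b - 1L) * cfg$batch_size + 1L):
                    min(b * cfg$batch_size, length(ord))]
      x <- images_to_batch(pre[take], insz)
      y <- onehot_matrix(lab[take], classes)
      fwd <- net_fwd(model, x, "train")
      model$state <- fwd$state
      lg <- loss_and_grad(model, fwd$logits, y)
      t_step <- t_step + 1L
      if (!is.finite(lg$loss))
        stop(sprintf("non-finite loss at epoch %d, iteration %d", epoch,
                     t_step))
      bwd <- net_bwd(model, fwd$caches, lg$dlogits)
      upd <- adam_step(model$params, bwd$grads, m_state, v_state,
                       cfg$learning_rate, t_step)
      model$params <- upd$p; m_state <- upd$m; v_state <- upd$v
      tot_loss <- tot_loss + lg$loss * length(take)
      tot_correct <- tot_correct +
        sum(max.col(t(lg$probs), ties.method = "first") ==
              match(lab[take], classes))
    }
    train_loss <- tot_loss / length(ord)
    train_acc <- tot_correct / length(ord)

    val_idx <- if (length(idx_val) > 0L) idx_val else idx_train
    val <- eval_pass(model, pre[val_idx], lab[val_idx], classes, insz,
                     cfg$batch_size)
    hist[[epoch]] <- data.frame(epoch = epoch, iteration = t_step,
                                train_loss = train_loss,
                                train_acc = train_acc,
                                val_loss = val$loss, val_acc = val$acc)
    line <- sprintf(
      "epoch %3d | iter %5d | train loss %.4f acc %.4f | val loss %.4f acc %.4f",
      epoch, t_step, train_loss, train_acc, val$loss, val$acc)
    if (verbose) message(line)
    if (!is.null(log_file)) cat(line, "\n", file = log_file, append = TRUE)
    if (val$acc > best$acc ||
        (val$acc == best$acc && val$loss < best$loss)) {
      best <- list(acc = val$acc, loss = val$loss, params = model$params,
                   state = model$state)
    }
  }
  model$params <- best$params
  model$state <- best$state
  list(model = model, history = do.call(rbind, hist))
}

eval_pass <- function(model, images, lab, classes, insz, batch_size) {
  n <- length(images)
  tot_loss <- 0; correct <- 0L
  pred <- integer(n)
  probs_all <- matrix(0, length(classes), n)
  for (b in seq_len(ceiling(n / batch_size))) {
    take <- ((b - 1L) * batch_size + 1L):min(b * batch_size, n)
    x <- images_to_batch(images[take], insz)
    fwd <- net_fwd(model, x, "eval")
    lg <- loss_and_grad(model, fwd$logits, onehot_matrix(lab[take], classes))
    tot_loss <- tot_loss + lg$loss * length(take)
    p <- max.col(t(lg$probs), ties.method = "first")
    pred[take] <- p
    probs_all[, take] <- lg$probs
    correct <- correct + sum(p == match(lab[take], classes))
  }
  list(loss = tot_loss / n, acc = correct / n, pred = classes[pred],
       probs = probs_all)
}

#' Evaluate a trained model on one split
#'
#' @param model a trained `ddrnet_model`.
#' @param data a [labeled_image_set()] with split tags.
#' @param split split tag to evaluate (default `"test"`).
#' @param batch_size evaluation batch size.
#' @return List with `confusion` (a [confusion_matrix()]) and `metrics`
#'   (a [metrics_report()]); all metrics derive solely from the confusion
#'   matrix.
#' @export
evaluate_model <- function(model, data, split = "test", batch_size = 32L) {
  idx <- if (is.null(data$split)) seq_along(data$images) else
    which(data$split == split)
  if (length(idx) == 0L) stop(sprintf("split '%s' is empty", split))
  classes <- class_names_for(model$config$num_classes)
  insz <- model$config$input_size
  ev <- eval_pass(model, data$images[idx], as.character(data$labels)[idx],
                  classes, insz, batch_size)
  cm <- confusion_matrix(as.character(data$labels)[idx], ev$pred,
                         classes = classes)
  list(confusion = cm, metrics = metrics_report(cm))
}

#' Class scores and predicted labels for images
#'
#' @param model a trained `ddrnet_model`.
#' @param images a list of images, a single (H, W, C) image, or an
#'   (H, W, C, N) batch.
#' @param batch_size batch size for the forward passes.
#' @return List with `scores` (N x K matrix; with the softmax head each row
#'   sums to 1) and `labels` (predicted class per image; ties broken toward
#'   the lowest class index).
#' @export
prediction_scores <- function(model, images, batch_size = 32L) {
  if (is.array(images) && length(dim(images)) == 3L) images <- list(images)
  if (is.array(images) && length(dim(images)) == 4L) {
    n <- dim(images)[4L]
    images <- lapply(seq_len(n), function(i) images[, , , i])
  }
  classes <- class_names_for(model$config$num_classes)
  insz <- model$config$input_size
  n <- length(images)
  scores <- matrix(0, n, length(classes),
                   dimnames = list(NULL, classes))
  for (b in seq_len(ceiling(n / batch_size))) {
    take <- ((b - 1L) * batch_size + 1L):min(b * batch_size, n)
    x <- images_to_batch(images[take], insz)
    fwd <- net_fwd(model, x, "eval")
    scores[take, ] <- t(fwd$probs)
  }
  labels <- classes[max.col(scores, ties.method = "first")]
  list(scores = scores, labels = labels)
}
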