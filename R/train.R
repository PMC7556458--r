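#' Image preprocessing and augmentation
#'
#' Evaluation phase: centre square crop, resize to `target_size`, rescale
#' from \[0, 1\] to \[-1, 1\]. Training phase: random crop covering at
#' least one third of the image area with aspect ratio in \[3/4, 4/3\],
#' random left-right flip, small brightness (+-0.1), saturation and
#' contrast (x 0.9-1.1) jitter, resize, rescale. Training-phase randomness
#' comes from the R random stream, so it is reproducible under `set.seed()`.
#'
#' @param image Array (height, width, channels) with values in \[0, 1\].
#' @param phase `"eval"` or `"train"`.
#' @param target_size Output spatial size in pixels (square).
#' @return Array (target_size, target_size, channels) with values in
#'   \[-1, 1\].
#' @export
preprocess <- function(image, phase = c("eval", "train"), target_size = dim(image)[1]) {
  phase <- match.arg(phase)
  d <- dim(image)
  if (length(d) == 2L) { dim(image) <- c(d, 1L); d <- dim(image) }
  if (d[1] < 2L || d[2] < 2L) stop("image smaller than 2x2")
  h <- d[1]; w <- d[2]
  if (phase == "eval") {
    s <- min(h, w)
    i0 <- (h - s) %/% 2L; j0 <- (w - s) %/% 2L
    crop <- image[i0 + seq_len(s), j0 + seq_len(s), , drop = FALSE]
  } else {
    a <- stats::runif(1, 1 / 3, 1)
    r <- stats::runif(1, 3 / 4, 4 / 3)
    ch <- max(1L, min(h, round(sqrt(a * h * w * r))))
    cw <- max(1L, min(w, round(sqrt(a * h * w / r))))
    i0 <- sample.int(h - ch + 1L, 1L) - 1L
    j0 <- sample.int(w - cw + 1L, 1L) - 1L
    crop <- image[i0 + seq_len(ch), j0 + seq_len(cw), , drop = FALSE]
    if (stats::runif(1) < 0.5) crop <- crop[, rev(seq_len(ncol(crop))), , drop = FALSE]
    crop <- crop + stats::runif(1, -0.1, 0.1)              # brightness
    gray <- array(rep(rowMeans(matrix(crop, ncol = dim(crop)[3])), dim(crop)[3]),
                  dim(crop))
    crop <- gray + stats::runif(1, 0.9, 1.1) * (crop - gray)  # saturation
    crop <- mean(crop) + stats::runif(1, 0.9, 1.1) * (crop - mean(crop))  # contrast
    crop[crop < 0] <- 0; crop[crop > 1] <- 1
  }
  out <- resize_bilinear(crop, target_size, target_size)
  2 * out - 1
}

resize_bilinear <- function(x, h, w) {
  if (dim(x)[1] == h && dim(x)[2] == w) return(x)
  y <- EBImage::resize(x, w = h, h = w)
  y <- as.array(y)
  dim(y) <- c(h, w, dim(x)[3])
  y
}

#' Multi-readout cross-entropy loss
#'
#' The training loss for networks with a readout at every time step: the
#' cross-entropy between each per-time-step softmax readout and the one-hot
#' label, averaged first over the batch and then across readouts. For T = 1
#' this is the ordinary cross-entropy.
#'
#' @param seq A [readout_sequence()] or a (batch, T, classes) probability
#'   array.
#' @param labels Integer class labels in 1..n_classes.
#' @return Mean cross-entropy in nats.
#' @export
multi_readout_loss <- function(seq, labels) {
  probs <- if (inherits(seq, "readout_sequence")) seq$probs else seq
  stopifnot(length(dim(probs)) == 3L, dim(probs)[1] == length(labels))
  if (any(labels < 1L | labels > dim(probs)[3])) stop("label outside class range")
  tt <- dim(probs)[2]
  ce <- vapply(seq_len(tt), function(t) {
    p <- probs[, t, , drop = FALSE][cbind(seq_along(labels), 1L, labels)]
    -mean(log(pmax(p, 1e-12)))
  }, numeric(1))
  mean(ce)
}

# loss + gradients for one minibatch; returns grads (named like params),
# loss value, and updated batch-norm running statistics
rcnn_loss_grad <- function(net, x, labels, l2 = 0, geoms = NULL) {
  spec <- net$spec
  if (is.null(geoms)) geoms <- net_geoms(spec)
  fw <- rcnn_forward(net, x, mode = "train", keep_cache = TRUE, geoms = geoms)
  nb <- length(spec$blocks); tt <- spec$n_timesteps
  n_img <- dim(x)[4]
  params <- net$params
  grads <- list()
  addg <- function(key, val) {
    grads[[key]] <<- if (is.null(grads[[key]])) val else grads[[key]] + val
  }
  dH <- lapply(seq_len(tt), function(t) vector("list", nb))
  addH <- function(t, n, val) {
    dH[[t]][[n]] <<- if (is.null(dH[[t]][[n]])) val else dH[[t]][[n]] + val
  }

  loss <- multi_readout_loss(fw$probs, labels)

  for (t in rev(seq_len(tt))) {
    rc <- fw$ro_caches[[t]]
    dlog <- rc$probs                                  # (classes, batch)
    dlog[cbind(labels, seq_len(n_img))] <- dlog[cbind(labels, seq_len(n_img))] - 1
    dlog <- dlog / (n_img * tt)
    addg(p_ro(spec, "W", t), rc$gap %*% t(dlog))
    addg(p_ro(spec, "b", t), rowSums(dlog))
    dgap <- params[[p_ro(spec, "W", t)]] %*% dlog     # (F_last, batch)
    addH(t, nb, gap_backward(dgap, rc$h_dim))

    for (n in rev(seq_len(nb))) {
      dy <- dH[[t]][[n]]
      if (is.null(dy)) next
      bc <- fw$caches[[t]]$blocks[[n]]
      g <- geoms[[n]]
      if (!is.null(bc$cache2)) {                      # B-D second stage
        c2 <- bc$cache2
        dz <- dy * c2$relu_mask
        bb <- bn_backward(dz, params[[paste0(bn_key(n, t, 2L), ".gamma")]], c2$bn)
        addg(paste0(bn_key(n, t, 2L), ".gamma"), bb$dgamma)
        addg(paste0(bn_key(n, t, 2L), ".beta"), bb$dbeta)
        cb <- conv_backward(bb$dx, c2$a_bu, params[[paste0("b", n, ".Wb2")]],
                            g$bu2, need_dx = TRUE)
        addg(paste0("b", n, ".Wb2"), cb$dw)
        dy <- cb$dx
      }
      c1 <- bc$cache1
      dz <- dy * c1$relu_mask
      bb <- bn_backward(dz, params[[paste0(bn_key(n, t, 1L), ".gamma")]], c1$bn)
      addg(paste0(bn_key(n, t, 1L), ".gamma"), bb$dgamma)
      addg(paste0(bn_key(n, t, 1L), ".beta"), bb$dbeta)
      # bottom-up branch
      cb <- conv_backward(bb$dx, c1$a_bu, params[[p_wb(spec, n, t)]],
                          g$bu, need_dx = n > 1L)
      addg(p_wb(spec, n, t), cb$dw)
      if (n > 1L) {
        dx <- cb$dx
        if (spec$blocks[[n - 1L]]$followed_by_pool)
          dx <- maxpool_backward(dx, fw$caches[[t]]$pools[[n - 1L]])
        addH(t, n - 1L, dx)
      }
      # lateral branch (absent at t = 1: zero initial state)
      if (!is.null(c1$a_lat)) {
        cl <- conv_backward(bb$dx, c1$a_lat, params[[p_wl(spec, n, t)]],
                            g$lat, need_dx = t > 1L)
        addg(p_wl(spec, n, t), cl$dw)
        if (t > 1L) addH(t - 1L, n, cl$dx)
      }
    }
  }

  if (l2 > 0) {
    for (key in names(params)) {
      if (grepl("\\.Wb|\\.Wl|readout\\.W", key)) {
        loss <- loss + l2 * sum(params[[key]]^2)
        g0 <- grads[[key]]
        grads[[key]] <- (if (is.null(g0)) 0 else g0) + 2 * l2 * params[[key]]
      }
    }
  }
  list(loss = loss, grads = grads, state = fw$state, probs = fw$probs)
}

#' Training configuration
#'
#' Defaults mirror the published full-scale recipe (90 epochs, batch 100,
#' Adam with learning rate 0.005 and epsilon 0.1, L2 coefficient 1e-6);
#' desk-scale runs override them.
#'
#' @param epochs,batch_size,learning_rate,adam_epsilon,l2_coefficient,seed
#'   Optimisation settings.
#' @param augment Apply training-phase augmentation ([preprocess()]).
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 90L, batch_size = 100L, learning_rate = 0.005,
                         adam_epsilon = 0.1, l2_coefficient = 1e-6, seed = 1L,
                         augment = TRUE) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0, adam_epsilon > 0,
            l2_coefficient >= 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, adam_epsilon = adam_epsilon,
                 l2_coefficient = l2_coefficient, seed = as.integer(seed),
                 augment = isTRUE(augment)), class = "train_config")
}

adam_update <- function(params, grads, opt, lr, eps, b1 = 0.9, b2 = 0.999) {
  opt$t <- opt$t + 1L
  for (key in names(grads)) {
    g <- grads[[key]]
    if (is.null(opt$m[[key]])) { opt$m[[key]] <- g * 0; opt$v[[key]] <- g * 0 }
    opt$m[[key]] <- b1 * opt$m[[key]] + (1 - b1) * g
    opt$v[[key]] <- b2 * opt$v[[key]] + (1 - b2) * g * g
    mhat <- opt$m[[key]] / (1 - b1^opt$t)
    vhat <- opt$v[[key]] / (1 - b2^opt$t)
    params[[key]] <- params[[key]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}

#' Train a network on an image dataset
#'
#' Optimises the multi-readout cross-entropy (see [multi_readout_loss()])
#' with Adam, per-time-step batch normalisation, and optional L2
#' regularisation. If `data` has no validation part, a fixed 80/20 split is
#' drawn from `config$seed`. The whole run is reproducible given the seed.
#'
#' @param spec An `rcnn_spec`.
#' @param data List with `x` (height, width, channels, n images, values in
#'   \[0, 1\]) and `y` (integer labels 1..n_classes); optionally `x_val`,
#'   `y_val`. A dataset from [synth_task()] works directly.
#' @param config A [train_config()].
#' @return An object of class `c("rcnn_fit", "rcnn_net")` with the trained
#'   parameters, batch-norm state, the `config`, and `log` — a data frame
#'   with one row per epoch and split (columns `epoch`, `split`, `loss`,
#'   `accuracy`; validation accuracy uses the cumulative readout at the
#'   final time step, evaluation-mode statistics).
#' @export
rcnn_train <- function(spec, data, config = train_config()) {
  stopifnot(inherits(spec, "rcnn_spec"))
  set.seed(config$seed)
  x <- data$x; y <- as.integer(data$y)
  stopifnot(length(dim(x)) == 4L, dim(x)[4] == length(y))
  if (is.null(data$x_val)) {
    n <- length(y)
    idx <- sample.int(n)
    n_tr <- floor(0.8 * n)
    tr <- idx[seq_len(n_tr)]; va <- idx[-seq_len(n_tr)]
    x_val <- x[, , , va, drop = FALSE]; y_val <- y[va]
    x <- x[, , , tr, drop = FALSE]; y <- y[tr]
  } else {
    x_val <- data$x_val; y_val <- as.integer(data$y_val)
  }
  target <- spec$input_size[1]
  net <- rcnn_init(spec, seed = config$seed)
  geoms <- net_geoms(spec)
  opt <- list(t = 0L, m = list(), v = list())
  n_tr <- length(y)
  xe_val <- preprocess_batch(x_val, "eval", target)
  log_rows <- list()

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n_tr)
    ep_loss <- 0; ep_correct <- 0
    for (start in seq(1L, n_tr, by = config$batch_size)) {
      ids <- ord[start:min(start + config$batch_size - 1L, n_tr)]
      xb <- preprocess_batch(x[, , , ids, drop = FALSE],
                             if (config$augment) "train" else "eval", target)
      lg <- rcnn_loss_grad(net, xb, y[ids], l2 = config$l2_coefficient,
                           geoms = geoms)
      if (!is.finite(lg$loss))
        stop(sprintf("training diverged (loss %s) at epoch %d", lg$loss, epoch))
      net$state <- lg$state
      upd <- adam_update(net$params, lg$grads, opt,
                         config$learning_rate, config$adam_epsilon)
      net$params <- upd$params; opt <- upd$opt
      ep_loss <- ep_loss + lg$loss * length(ids)
      pred <- apply(apply(lg$probs, c(1, 3), mean), 1, which.max)  # cumulative
      ep_correct <- ep_correct + sum(pred == y[ids])
    }
    val_seq <- rcnn_forward(net, xe_val, mode = "eval", geoms = geoms)$probs
    val_pred <- apply(apply(val_seq, c(1, 3), mean), 1, which.max)
    val_loss <- multi_readout_loss(val_seq, y_val)
    log_rows[[epoch]] <- data.frame(
      epoch = epoch, split = c("train", "val"),
      loss = c(ep_loss / n_tr, val_loss),
      accuracy = c(ep_correct / n_tr, mean(val_pred == y_val)))
  }
  net$config <- config
  net$log <- do.call(rbind, log_rows)
  class(net) <- c("rcnn_fit", "rcnn_net")
  net
}

#' @rdname preprocess
#' @param x Image batch (height, width, channels, n).
#' @export
preprocess_batch <- function(x, phase, target) {
  n <- dim(x)[4]
  out <- array(0, c(target, target, dim(x)[3], n))
  for (i in seq_len(n))
    out[, , , i] <- preprocess(x[, , , i, drop = TRUE], phase, target)
  out
}

#' @export
print.rcnn_fit <- function(x, ...) {
  NextMethod()
  fin <- x$log[x$log$epoch == max(x$log$epoch), ]
  cat(sprintf("  trained %d epochs | final train acc %.3f | val acc %.3f\n",
              max(x$log$epoch), fin$accuracy[fin$split == "train"],
              fin$accuracy[fin$split == "val"]))
  invisible(x)
}

#' @export
plot.rcnn_fit <- function(x, ...) {
  log <- x$log
  graphics::plot(NULL, xlim = range(log$epoch), ylim = c(0, 1),
                 xlab = "epoch", ylab = "accuracy",
                 main = sprintf("%s training", x$spec$family))
  for (s in unique(log$split)) {
    sub <- log[log$split == s, ]
    graphics::lines(sub$epoch, sub$accuracy, lty = if (s == "train") 1 else 2)
  }
  graphics::legend("bottomright", legend = unique(log$split),
                   lty = seq_along(unique(log$split)), bty = "n")
  invisible(x)
}
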