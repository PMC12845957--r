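# Training loop: AdamW with decoupled weight decay, an optional linear
# warm-up + cosine decay schedule, early stopping on validation loss, and
# best-validation-loss checkpointing.

#' Training configuration
#'
#' Defaults per architecture: the CNN trains 10 epochs at a constant
#' 1e-3 learning rate; the ViT trains up to 30 epochs with a 2-epoch linear
#' warm-up followed by cosine decay, early stopping with patience 5 on
#' validation loss, and best-checkpoint restoration. Both use AdamW
#' (decoupled weight decay 0.004), batch size 128, and sparse categorical
#' cross-entropy.
#'
#' @param arch `"cnn"` or `"vit"`; selects the per-architecture defaults.
#' @param base_lr peak learning rate.
#' @param weight_decay decoupled weight decay coefficient.
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param warmup_epochs linear warm-up length (with `schedule = "warmup_cosine"`).
#' @param schedule `"constant"` or `"warmup_cosine"`.
#' @param early_stopping_patience epochs without validation-loss improvement
#'   before stopping; `NULL` disables early stopping.
#' @param seed integer seed covering shuffling and dropout.
#' @return list of class `train_config`.
#' @export
train_config <- function(arch = c("cnn", "vit"),
                         base_lr = 1e-3,
                         weight_decay = 0.004,
                         batch_size = 128L,
                         max_epochs = if (arch == "cnn") 10L else 30L,
                         warmup_epochs = if (arch == "cnn") 0L else 2L,
                         schedule = if (arch == "cnn") "constant" else "warmup_cosine",
                         early_stopping_patience = if (arch == "cnn") NULL else 5L,
                         seed = 1L) {
  arch <- match.arg(arch)
  if (base_lr <= 0 || weight_decay < 0 || batch_size < 1L) {
    stop("rates must be positive")
  }
  if (warmup_epochs >= max_epochs && schedule == "warmup_cosine") {
    stop("warmup_epochs must be smaller than max_epochs")
  }
  structure(list(arch = arch, base_lr = base_lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 warmup_epochs = as.integer(warmup_epochs),
                 schedule = schedule,
                 early_stopping_patience = early_stopping_patience,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given optimizer step
#'
#' With the warm-up + cosine schedule the rate ramps linearly from 0 to
#' `base_lr` across the warm-up steps, then decays as
#' `base_lr * (1 + cos(pi * progress)) / 2` over the remaining steps, reaching
#' 0 at `total_steps`. The profile is continuous at the boundary and
#' non-increasing afterwards. A `"constant"` schedule returns `base_lr`
#' everywhere.
#'
#' @param step optimizer step in `[0, total_steps]`.
#' @param total_steps total planned steps.
#' @param cfg a [train_config()].
#' @return learning rate.
#' @export
lr_at <- function(step, total_steps, cfg) {
  if (any(step < 0) || any(step > total_steps)) stop("step out of range")
  if (cfg$schedule == "constant") return(rep_len(cfg$base_lr, length(step)))
  warm <- cfg$warmup_epochs / cfg$max_epochs * total_steps
  ifelse(step < warm,
         cfg$base_lr * step / warm,
         {
           progress <- (step - warm) / (total_steps - warm)
           cfg$base_lr * 0.5 * (1 + cos(pi * progress))
         })
}

# AdamW state handle over the model's leaf layers.
adamw_init <- function(layers) {
  lapply(layers, function(L) {
    lapply(L$params, function(p) list(m = array(0, dim(p) %||% length(p)),
                                      v = array(0, dim(p) %||% length(p))))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adamw_step <- function(layers, state, lr, weight_decay, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    L <- layers[[i]]
    for (nm in names(L$params)) {
      g <- L$grads[[nm]]
      if (is.null(g)) next
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      upd <- (st$m / bc1) / (sqrt(st$v / bc2) + eps)
      p <- L$params[[nm]] - lr * upd
      if (nm %in% L$decay) p <- p - lr * weight_decay * L$params[[nm]]
      L$params[[nm]] <- p
      state[[i]][[nm]] <- st
    }
  }
  state
}

# cross-entropy of logits against integer labels (1-based); also returns
# the gradient w.r.t. logits and the accuracy.
ce_loss <- function(logits, y) {
  n <- nrow(logits)
  zmax <- apply(logits, 1L, max)
  lse <- zmax + log(rowSums(exp(logits - zmax)))
  logp <- logits - lse
  loss <- -mean(logp[cbind(seq_len(n), y)])
  p <- exp(logp)
  grad <- p
  grad[cbind(seq_len(n), y)] <- grad[cbind(seq_len(n), y)] - 1
  list(loss = loss, grad = grad / n, acc = mean(max.col(p, "first") == y))
}

# checkpoint trainable parameters plus normalization running state
snapshot_params <- function(layers) {
  lapply(layers, function(L) {
    s <- list(params = L$params)
    if (!is.null(L$running_mean)) {
      s$running_mean <- L$running_mean
      s$running_var <- L$running_var
      s$steps <- L$steps
      s$frozen <- L$frozen
    }
    s
  })
}

restore_params <- function(layers, snap) {
  for (i in seq_along(layers)) {
    layers[[i]]$params <- snap[[i]]$params
    if (!is.null(snap[[i]]$running_mean)) {
      layers[[i]]$running_mean <- snap[[i]]$running_mean
      layers[[i]]$running_var <- snap[[i]]$running_var
      layers[[i]]$steps <- snap[[i]]$steps
      layers[[i]]$frozen <- snap[[i]]$frozen
    }
  }
  invisible(NULL)
}

# Recompute batch-norm inference statistics over `x` with dropout inactive
# ("precise BN"). No-op for models without batch norm (e.g. the ViT).
recalibrate_bn <- function(model, x, batch_size = 128L) {
  bns <- Filter(function(L) L$type == "batchnorm", leaf_layers(model$layers))
  if (length(bns) == 0L) return(invisible(model))
  for (L in bns) {
    L$collect <- TRUE
    nc <- length(L$params$gamma)
    L$acc_sum <- numeric(nc)
    L$acc_sumsq <- numeric(nc)
    L$acc_n <- 0
  }
  n <- dim(x)[4L]
  for (b in seq_len(ceiling(n / batch_size))) {
    idx <- ((b - 1L) * batch_size + 1L):min(b * batch_size, n)
    forward_model(model, x[, , , idx, drop = FALSE], training = FALSE)
  }
  for (L in bns) {
    mu <- L$acc_sum / L$acc_n
    L$frozen <- list(mean = mu, var = pmax(L$acc_sumsq / L$acc_n - mu^2, 0))
    L$collect <- FALSE
  }
  invisible(model)
}

# loss/accuracy over a dataset in eval mode, in batches
evaluate_loss <- function(model, x, y, batch_size = 128L) {
  n <- dim(x)[4L]
  tot_loss <- 0
  tot_correct <- 0
  for (b in seq_len(ceiling(n / batch_size))) {
    idx <- ((b - 1L) * batch_size + 1L):min(b * batch_size, n)
    logits <- forward_model(model, x[, , , idx, drop = FALSE], training = FALSE)
    r <- ce_loss(logits, y[idx])
    tot_loss <- tot_loss + r$loss * length(idx)
    tot_correct <- tot_correct + r$acc * length(idx)
  }
  list(loss = tot_loss / n, acc = tot_correct / n)
}

#' Train a classifier
#'
#' Minimizes sparse categorical cross-entropy with AdamW. Tracks per-epoch
#' training and validation loss/accuracy, checkpoints the weights with the
#' best validation loss, optionally stops early after
#' `early_stopping_patience` epochs without improvement, and restores the
#' checkpointed weights before returning. Reproducible given
#' `cfg$seed` (weight initialization is governed separately by the builder's
#' seed).
#'
#' @param model a `whale_model` from [build_cnn()] or [build_vit()].
#' @param train_x,train_y training images (125 x 50 x 3 x N array,
#'   standardized) and integer labels (1 = humpback, 2 = no_call).
#' @param val_x,val_y validation images and labels.
#' @param cfg a [train_config()].
#' @param verbose print per-epoch progress.
#' @return the model, with a `history` element: data.frame (epoch,
#'   train_loss, train_acc, val_loss, val_acc) plus attribute `best_epoch`.
#' @export
train_model <- function(model, train_x, train_y, val_x, val_y,
                        cfg = train_config(model$arch), verbose = FALSE) {
  n <- dim(train_x)[4L]
  if (n == 0L || dim(val_x)[4L] == 0L) stop("empty dataset")
  if (length(train_y) != n) stop("label/image count mismatch")
  layers <- leaf_layers(model$layers)
  state <- adamw_init(layers)
  steps_per_epoch <- ceiling(n / cfg$batch_size)
  total_steps <- cfg$max_epochs * steps_per_epoch
  step <- 0L
  best_loss <- Inf
  best_epoch <- NA_integer_
  best_snap <- NULL
  hist <- list()
  set.seed(cfg$seed)
  for (epoch in seq_len(cfg$max_epochs)) {
    idx <- sample.int(n)
    ep_loss <- 0
    ep_acc <- 0
    for (b in seq_len(steps_per_epoch)) {
      bi <- idx[((b - 1L) * cfg$batch_size + 1L):min(b * cfg$batch_size, n)]
      logits <- forward_model(model, train_x[, , , bi, drop = FALSE],
                              training = TRUE)
      r <- ce_loss(logits, train_y[bi])
      if (!is.finite(r$loss)) {
        stop(sprintf("NaN/Inf loss at epoch %d step %d; aborting", epoch, b))
      }
      backward_model(model, r$grad)
      lr <- lr_at(step, total_steps, cfg)
      step <- step + 1L
      state <- adamw_step(layers, state, lr, cfg$weight_decay, step)
      ep_loss <- ep_loss + r$loss * length(bi)
      ep_acc <- ep_acc + r$acc * length(bi)
    }
    recalibrate_bn(model, train_x, cfg$batch_size)
    val <- evaluate_loss(model, val_x, val_y, cfg$batch_size)
    hist[[epoch]] <- data.frame(epoch = epoch,
                                train_loss = ep_loss / n,
                                train_acc = ep_acc / n,
                                val_loss = val$loss, val_acc = val$acc)
    if (verbose) {
      message(sprintf("epoch %2d: loss %.4f acc %.3f | val loss %.4f acc %.3f",
                      epoch, ep_loss / n, ep_acc / n, val$loss, val$acc))
    }
    if (val$loss < best_loss) {
      best_loss <- val$loss
      best_epoch <- epoch
      best_snap <- snapshot_params(layers)
    }
    if (!is.null(cfg$early_stopping_patience) &&
        epoch - best_epoch >= cfg$early_stopping_patience) {
      break
    }
  }
  if (!is.null(best_snap)) restore_params(layers, best_snap)
  history <- do.call(rbind, hist)
  attr(history, "best_epoch") <- best_epoch
  model$history <- history
  model$train_config <- cfg
  model
}

#' Predict class probabilities for feature images
#'
#' @param object a trained `whale_model`.
#' @param images a 125 x 50 x 3 x N array, a list of `feature_image`s, or a
#'   single image. Images should be per-image standardized; a warning is
#'   issued when they appear not to be.
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return N x 2 matrix of class probabilities (columns `humpback`,
#'   `no_call`), each row summing to 1.
#' @export
predict.whale_model <- function(object, images, batch_size = 128L, ...) {
  x <- as_image_batch(images)
  n <- dim(x)[4L]
  probs <- matrix(0, n, length(object$classes),
                  dimnames = list(NULL, object$classes))
  for (b in seq_len(ceiling(n / batch_size))) {
    idx <- ((b - 1L) * batch_size + 1L):min(b * batch_size, n)
    logits <- forward_model(object, x[, , , idx, drop = FALSE], training = FALSE)
    probs[idx, ] <- softmax_rows(logits)
  }
  probs
}

#' @export
predict.whale_external_model <- function(object, images, ...) {
  p <- object$predict_fn(as_image_batch(images))
  colnames(p) <- object$classes
  p
}

# normalize user-supplied images to a (125, 50, 3, N) array
as_image_batch <- function(images) {
  if (is.list(images)) {
    flagged <- vapply(images, function(im) {
      isFALSE(attr(im, "standardized"))
    }, TRUE)
    if (any(flagged)) {
      warning("images are not per-image standardized; call standardize_image()")
    }
    x <- array(0, c(dim(images[[1L]]), length(images)))
    for (i in seq_along(images)) x[, , , i] <- unclass(images[[i]])
    x
  } else if (length(dim(images)) == 3L) {
    if (isFALSE(attr(images, "standardized"))) {
      warning("image is not per-image standardized; call standardize_image()")
    }
    array(unclass(images), c(dim(images), 1L))
  } else if (length(dim(images)) == 4L) {
    unclass(images)
  } else {
    stop("images must be an array of 3 or 4 dimensions, or a list of images")
  }
}
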