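# Training: class-reweighted label-smoothed cross-entropy, AdamW with
# warmup-cosine learning rate and global-norm clipping, curriculum-
# driven augmentation, early stopping with best-checkpoint restore.

#' Training configuration
#'
#' Defaults follow the published recipe: batch size 8, up to 50 epochs,
#' base learning rate 3e-4 decayed to a 1e-6 floor by a warmup-cosine
#' schedule (warmup = 10% of total steps), AdamW decoupled weight decay
#' 1e-4, global gradient-norm clip 1.0, early stopping on validation
#' accuracy with patience 12, MixUp/CutMix Beta concentration 0.3.
#'
#' @param batch_size Mini-batch size (>= 2; batch pairing needs it).
#' @param max_epochs Maximum epochs.
#' @param base_lr,min_lr Peak and floor learning rates.
#' @param warmup_frac Warmup fraction of total steps, in (0, 1).
#' @param weight_decay AdamW decoupled weight decay.
#' @param clipnorm Global gradient-norm ceiling.
#' @param patience Early-stopping patience (epochs without val-accuracy
#'   improvement).
#' @param mixup_alpha Beta(alpha, alpha) concentration for MixUp.
#' @param seed RNG seed for the whole run.
#' @param beta1,beta2,adam_eps AdamW moment constants.
#' @param augment Apply geometric/photometric jitter to training
#'   batches (disable for pure overfitting probes).
#' @param class_weighting Weight samples by inverse class frequency
#'   (disable to ablate the reweighting mechanism).
#' @param curriculum Optional curriculum override table for
#'   [curriculum_at()].
#' @return List of class `train_config`.
#' @export
train_config <- function(batch_size = 8L, max_epochs = 50L, base_lr = 3e-4,
                         min_lr = 1e-6, warmup_frac = 0.10,
                         weight_decay = 1e-4, clipnorm = 1.0,
                         patience = 12L, mixup_alpha = 0.3, seed = 42L,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-7,
                         augment = TRUE, class_weighting = TRUE,
                         curriculum = NULL) {
  stopifnot(warmup_frac > 0, warmup_frac < 1, batch_size >= 2L,
            patience <= max_epochs)
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), base_lr = base_lr,
                 min_lr = min_lr, warmup_frac = warmup_frac,
                 weight_decay = weight_decay, clipnorm = clipnorm,
                 patience = as.integer(patience), mixup_alpha = mixup_alpha,
                 seed = as.integer(seed), beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps, augment = isTRUE(augment),
                 class_weighting = isTRUE(class_weighting),
                 curriculum = curriculum),
            class = "train_config")
}

#' Inverse-frequency class weights
#'
#' `w_k = N / (K * n_k)`, so the expected per-class contribution to the
#' loss is uniform and `sum_k w_k * n_k = N` exactly. Balanced counts
#' give all-ones.
#'
#' @param counts Named or plain vector of positive per-class counts.
#' @return Numeric weight vector (names preserved).
#' @export
#' @examples
#' class_weights(c(100, 50, 25, 25))
class_weights <- function(counts) {
  if (any(counts <= 0)) stop("all class counts must be > 0")
  N <- sum(counts)
  K <- length(counts)
  N / (K * counts)
}

#' Warmup-cosine learning rate
#'
#' Linear warmup `eta0 * t / T_w` over the first `T_w =
#' warmup_frac * total_steps` steps, then half-amplitude cosine decay
#' `eta_min + 0.5 * (eta0 - eta_min) * (1 + cos(pi * (t - T_w) / T_d))`
#' with `T_d = total_steps - T_w`, so the rate is `eta0` at the end of
#' warmup, monotone non-increasing afterwards and exactly `eta_min` at
#' the final step.
#'
#' @param t Step index in `[0, total_steps]`.
#' @param total_steps Total planned optimizer steps (> 0).
#' @param cfg A [train_config()] (uses `base_lr`, `min_lr`,
#'   `warmup_frac`).
#' @return Learning rate.
#' @export
lr_at <- function(t, total_steps, cfg = train_config()) {
  if (total_steps <= 0) stop("total_steps must be > 0")
  Tw <- cfg$warmup_frac * total_steps
  Td <- total_steps - Tw
  if (t < Tw) return(cfg$base_lr * t / Tw)
  cfg$min_lr + 0.5 * (cfg$base_lr - cfg$min_lr) * (1 + cos(pi * (t - Tw) / Td))
}

#' Label-smoothed, class-weighted cross-entropy
#'
#' Targets are smoothed as `ytilde = (1 - eps) * y + eps / K` (mixed
#' labels allowed; rows must sum to 1). Each sample is weighted by its
#' label-mass-weighted class weight `sum_k y_k * w_k` and the batch
#' loss is the mean of the weighted per-sample cross-entropies.
#' Probabilities are clipped to `[1e-7, 1]` before the log.
#'
#' @param y N x K label matrix (one-hot or mixed), rows summing to 1.
#' @param p N x K probability matrix, rows summing to 1.
#' @param eps Smoothing coefficient in \[0, 1).
#' @param w Class weight vector (default all ones).
#' @return List with `loss` (scalar), `sample_weights`, and `y_smooth`.
#' @export
smoothed_weighted_ce <- function(y, p, eps = 0, w = rep(1, ncol(y))) {
  if (any(p < 0) || any(y < 0)) stop("negative entries in p or y")
  stopifnot(eps >= 0, eps < 1)
  K <- ncol(y)
  ys <- (1 - eps) * y + eps / K
  sw <- as.vector(y %*% w)
  ce <- -rowSums(ys * log(pmin(pmax(p, 1e-7), 1)))
  list(loss = mean(sw * ce), sample_weights = sw, y_smooth = ys)
}

#' Clip gradients to a global L2 norm
#'
#' Computes the norm over every tensor in the (nested) gradient list
#' and rescales all of them by `max_norm / norm` when it exceeds
#' `max_norm`.
#'
#' @param grads Nested list of numeric arrays.
#' @param max_norm Norm ceiling.
#' @return List with `grads` (possibly rescaled) and `norm` (pre-clip
#'   global norm).
#' @export
clip_global_norm <- function(grads, max_norm) {
  sq <- 0
  walk <- function(g) {
    for (el in g) {
      if (is.list(el)) walk(el)
      else if (is.numeric(el)) sq <<- sq + sum(el * el)
    }
  }
  walk(grads)
  norm <- sqrt(sq)
  if (is.finite(norm) && norm > max_norm) {
    scale <- max_norm / norm
    rescale <- function(g) lapply(g, function(el)
      if (is.list(el)) rescale(el) else el * scale)
    grads <- rescale(grads)
  }
  list(grads = grads, norm = norm)
}

# one-hot encode integer labels in [1, K]
one_hot <- function(labels, K) {
  y <- matrix(0, length(labels), K)
  y[cbind(seq_along(labels), labels)] <- 1
  y
}

#' Load one manifest split as an in-memory image tensor
#'
#' Reads every record of a split, resizes to `size` x `size` (bilinear)
#' and stacks into an `(N, size, size, 3)` array with integer labels
#' indexed against the canonical class order.
#'
#' @param manifest A `split_manifest`.
#' @param split `"train"`, `"val"` or `"test"`.
#' @param size Target side length in pixels.
#' @return List with `x` (array), `y` (integer labels), `classes`,
#'   `paths`.
#' @export
load_split_images <- function(manifest, split = c("train", "val", "test"), size = 64L) {
  split <- match.arg(split)
  recs <- manifest[[split]]
  if (!nrow(recs)) stop("split '", split, "' is empty")
  x <- array(0, c(nrow(recs), size, size, 3L))
  for (i in seq_len(nrow(recs)))
    x[i, , , ] <- resize_bilinear(read_image(recs$path[i]), size, size)
  list(x = x, y = match(recs$label, CANONICAL_CLASSES),
       classes = CANONICAL_CLASSES, paths = recs$path)
}

# curriculum-gated augmentation of one aligned batch pair;
# returns the mixed training batch
.augment_pair <- function(ba, bb, policy, cfg) {
  n <- dim(ba$x)[1]
  for (i in seq_len(n)) {
    img <- ba$x[i, , , ]
    if (cfg$augment) img <- geometric_photometric(img)
    if (policy[["p_clahe"]] > 0 && stats::runif(1) < policy[["p_clahe"]])
      img <- apply_clahe(img)
    if (policy[["p_erase"]] > 0 && stats::runif(1) < policy[["p_erase"]])
      img <- random_erase(img)
    ba$x[i, , , ] <- img
  }
  # MixUp and CutMix are mutually exclusive per batch: one gate draw,
  # the applied variant chosen in proportion to their probabilities
  p_mix <- policy[["p_mixup"]] + policy[["p_cutmix"]]
  if (p_mix > 0 && stats::runif(1) < p_mix) {
    if (stats::runif(1) < policy[["p_mixup"]] / p_mix)
      return(mixup_batch(ba, bb, alpha = cfg$mixup_alpha))
    return(cutmix_batch(ba, bb))
  }
  ba
}

# AdamW update on one tensor; st carries (m, v)
.adamw_step <- function(par, grad, st, lr, cfg, t) {
  st$m <- cfg$beta1 * st$m + (1 - cfg$beta1) * grad
  st$v <- cfg$beta2 * st$v + (1 - cfg$beta2) * grad * grad
  mhat <- st$m / (1 - cfg$beta1^t)
  vhat <- st$v / (1 - cfg$beta2^t)
  par <- par - lr * (mhat / (sqrt(vhat) + cfg$adam_eps) + cfg$weight_decay * par)
  list(par = par, st = st)
}

#' Train the network
#'
#' Full training loop: per epoch the curriculum policy is queried,
#' index-aligned batch pairs are streamed, geometric/photometric
#' jitter, CLAHE, random erasing and MixUp/CutMix are applied per the
#' policy gates, and the class-reweighted smoothed cross-entropy is
#' optimized with AdamW under global-norm clipping and the
#' warmup-cosine learning rate (`total_steps = max_epochs *
#' steps_per_epoch`, fixed even if stopping fires earlier). Training
#' stops when validation accuracy has not improved for `patience`
#' epochs; the best-epoch weights are restored. The whole run is a
#' deterministic function of `(model, data, cfg$seed)`.
#'
#' @param model A freshly built `sepattnet_model`.
#' @param data List with `train` and `val`, each `list(x, y)` as
#'   produced by [load_split_images()].
#' @param cfg A [train_config()].
#' @return List of class `train_result`: `model` (best weights),
#'   `history` (per-epoch data.frame), `best_epoch`,
#'   `best_val_accuracy`.
#' @export
fit <- function(model, data, cfg = train_config()) {
  if (is.null(data$val) || length(data$val$y) == 0L) stop("val split is empty")
  K <- model$cfg$n_classes
  n_train <- length(data$train$y)
  steps_per_epoch <- n_train %/% cfg$batch_size
  if (steps_per_epoch < 1) stop("fewer training images than one batch")
  total_steps <- cfg$max_epochs * steps_per_epoch
  w <- if (cfg$class_weighting) class_weights(tabulate(data$train$y, nbins = K))
       else rep(1, K)
  ytr <- one_hot(data$train$y, K)
  set.seed(cfg$seed)
  # optimizer state parallel to the parameter tree
  opt <- lapply(model$layers, function(l)
    if (is.null(l$par)) NULL
    else lapply(l$par, function(p) list(m = p * 0, v = p * 0)))
  opt_pad <- if (!is.null(model$pad)) list(m = model$pad * 0, v = model$pad * 0) else NULL
  hist_rows <- list()
  best <- list(epoch = -1L, acc = -Inf, layers = model$layers, pad = model$pad)
  step <- 0L
  for (epoch in 0:(cfg$max_epochs - 1L)) {
    policy <- curriculum_at(epoch, cfg$curriculum)
    eps_ls <- policy[["eps_ls"]]
    pairs <- paired_batches(n_train, cfg$batch_size,
                            seed = cfg$seed + 7919L * (epoch + 1L))
    ep_loss <- 0; ep_correct <- 0; ep_n <- 0
    lr_epoch <- lr_at(step, total_steps, cfg)
    for (pb in pairs) {
      ba <- list(x = data$train$x[pb$i, , , , drop = FALSE], y = ytr[pb$i, , drop = FALSE])
      bb <- list(x = data$train$x[pb$j, , , , drop = FALSE], y = ytr[pb$j, , drop = FALSE])
      batch <- .augment_pair(ba, bb, policy, cfg)
      fw <- model_forward(model, batch$x, training = TRUE)
      model <- fw$model
      p <- fw$probs
      lo <- smoothed_weighted_ce(batch$y, p, eps = eps_ls, w = w)
      if (!is.finite(lo$loss))
        stop("non-finite loss at epoch ", epoch, ", step ", step,
             " (lr ", format(lr_at(step, total_steps, cfg)), ")")
      B <- nrow(p)
      dlogits <- lo$sample_weights * (p - lo$y_smooth) / B
      bw <- model_backward(model, fw$caches, dlogits)
      cl <- clip_global_norm(bw$grads, cfg$clipnorm)
      grads <- cl$grads
      lr <- lr_at(step, total_steps, cfg)
      step <- step + 1L
      for (li in seq_along(model$layers)) {
        if (is.null(grads[[li]])) next
        for (pn in names(grads[[li]])) {
          up <- .adamw_step(model$layers[[li]]$par[[pn]], grads[[li]][[pn]],
                            opt[[li]][[pn]], lr, cfg, step)
          model$layers[[li]]$par[[pn]] <- up$par
          opt[[li]][[pn]] <- up$st
        }
      }
      if (!is.null(opt_pad)) {
        up <- .adamw_step(model$pad, bw$dpad, opt_pad, lr, cfg, step)
        model$pad <- up$par
        opt_pad <- up$st
      }
      ep_loss <- ep_loss + lo$loss * B
      ep_correct <- ep_correct + sum(max.col(p) == max.col(batch$y))
      ep_n <- ep_n + B
    }
    vp <- predict_proba(model, data$val$x)
    vl <- smoothed_weighted_ce(one_hot(data$val$y, K), vp, eps = 0, w = w)
    val_acc <- mean(max.col(vp) == data$val$y)
    hist_rows[[length(hist_rows) + 1L]] <- data.frame(
      epoch = epoch, lr = lr_epoch,
      train_loss = ep_loss / ep_n, train_acc = ep_correct / ep_n,
      val_loss = vl$loss, val_acc = val_acc,
      p_mixup = policy[["p_mixup"]], p_cutmix = policy[["p_cutmix"]],
      p_erase = policy[["p_erase"]], p_clahe = policy[["p_clahe"]],
      eps_ls = eps_ls)
    if (val_acc > best$acc) {
      best <- list(epoch = epoch, acc = val_acc,
                   layers = model$layers, pad = model$pad)
    }
    if (epoch - best$epoch >= cfg$patience) break
  }
  model$layers <- best$layers
  model$pad <- best$pad
  structure(list(model = model, history = do.call(rbind, hist_rows),
                 best_epoch = best$epoch, best_val_accuracy = best$acc),
            class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  cat("Training run:", nrow(x$history), "epochs; best epoch", x$best_epoch,
      "with validation accuracy", sprintf("%.4f", x$best_val_accuracy), "\n")
  invisible(x)
}
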