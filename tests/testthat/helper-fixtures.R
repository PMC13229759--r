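# Shared fixtures: all built in code at test time.

# balanced phantom image set as an in-memory batch
phantom_set <- function(n, size = 64L, seed = 1000L) {
  x <- array(0, c(n, size, size, 3L))
  y <- integer(n)
  for (i in seq_len(n)) {
    cls <- CANONICAL_CLASSES[(i - 1L) %% 4L + 1L]
    x[i, , , ] <- make_phantom(cls, size = size, seed = seed + i)
    y[i] <- (i - 1L) %% 4L + 1L
  }
  list(x = x, y = y, classes = CANONICAL_CLASSES)
}

# smallest config that exercises every layer kind (16 px, 4 pools -> 1 px)
tiny_cfg <- function(n_classes = 3L, ...) {
  arch_config(input_size = 16L, stem_widths = c(3L, 4L),
              block_widths = c(5L, 6L, 7L), se_bottleneck = 2L,
              head_units = 5L, dropout = 0, noise_std = 0,
              n_classes = n_classes, param_target = NULL, ...)
}

# random rows on the probability simplex
rand_probs <- function(n, K) {
  p <- matrix(stats::rexp(n * K), n, K)
  p / rowSums(p)
}

# configuration of the optimization-capacity probe: stochastic
# regularizers off, augmentation off, learning rate scaled for the
# short desk-scale run
overfit_probe_cfg <- function(seed, max_epochs = 30L) {
  train_config(batch_size = 8L, max_epochs = max_epochs, base_lr = 3e-3,
               patience = max_epochs, seed = seed, augment = FALSE,
               curriculum = list(list(until = Inf,
                 policy = c(p_mixup = 0, p_cutmix = 0, p_erase = 0,
                            p_clahe = 0, eps_ls = 0))))
}
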