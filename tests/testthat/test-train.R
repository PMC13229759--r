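# Training: class weights, learning-rate schedule, smoothed weighted
# cross-entropy, gradient clipping, fit loop semantics.

test_that("inverse-frequency class weights balance expected loss mass", {
  expect_equal(class_weights(c(100, 100, 100, 100)), rep(1, 4))
  expect_equal(class_weights(c(100, 50, 25, 25)), c(0.5, 1, 2, 2))
  set.seed(1)
  for (i in 1:10) {
    counts <- sample(1:500, sample(2:6, 1))
    w <- class_weights(counts)
    expect_equal(sum(w * counts), sum(counts), tolerance = 1e-9)
  }
  expect_error(class_weights(c(10, 0)), "> 0")
})

test_that("warmup-cosine schedule hits its anchors and decays monotonically", {
  cfg <- train_config()
  total <- 1000
  Tw <- 100; Td <- 900
  expect_equal(lr_at(Tw, total, cfg), 3e-4)
  expect_equal(lr_at(total, total, cfg), 1e-6)
  # cosine midpoint: eta_min + (eta0 - eta_min)/2 = (eta0 + eta_min)/2
  expect_equal(lr_at(Tw + Td / 2, total, cfg), 1e-6 + 0.5 * (3e-4 - 1e-6))
  expect_equal(lr_at(Tw + Td / 2, total, cfg), 1.505e-4)
  expect_equal(lr_at(0, total, cfg), 0)
  expect_equal(lr_at(50, total, cfg), 1.5e-4)  # linear warmup midpoint
  # continuity at T_w and strict decay afterwards, bounded throughout
  lrs <- vapply(seq(0, total, by = 1), lr_at, numeric(1), total_steps = total, cfg = cfg)
  expect_lt(abs(lrs[Tw + 1] - lrs[Tw + 2]), 3e-4 * 0.01)
  after <- lrs[(Tw + 1):(total + 1)]
  expect_true(all(diff(after) < 0))
  expect_true(all(lrs >= 0 & lrs <= 3e-4 + 1e-15))
  expect_error(lr_at(0, 0, cfg), "> 0")
})

test_that("label smoothing and weighting enter the loss as specified", {
  # perfect one-hot prediction, no smoothing: loss at the clip floor
  y <- diag(4)
  lo <- smoothed_weighted_ce(y, y, eps = 0)
  expect_lt(lo$loss, 1e-6)
  # smoothed target for K = 4, eps = 0.05
  lo2 <- smoothed_weighted_ce(matrix(c(1, 0, 0, 0), 1), matrix(0.25, 1, 4), eps = 0.05)
  expect_equal(as.vector(lo2$y_smooth), c(0.9625, 0.0125, 0.0125, 0.0125))
  # uniform prediction: loss = ln K whatever the (unit-mass) target
  expect_equal(lo2$loss, log(4), tolerance = 1e-12)
  # loss at the optimum increases with smoothing
  losses <- vapply(c(0, 0.05, 0.1, 0.2), function(e)
    smoothed_weighted_ce(y, y, eps = e)$loss, numeric(1))
  expect_true(all(diff(losses) > 0))
  # sample weights are label-mass-weighted class weights
  w <- c(0.5, 1, 2, 2)
  mixed <- matrix(c(0.4, 0.6, 0, 0), 1)
  lo3 <- smoothed_weighted_ce(mixed, matrix(0.25, 1, 4), eps = 0, w = w)
  expect_equal(lo3$sample_weights, 0.4 * 0.5 + 0.6 * 1)
  expect_error(smoothed_weighted_ce(-y, y, 0), "negative")
})

test_that("global-norm clipping rescales exactly to the ceiling", {
  g <- list(list(W = matrix(3, 2, 2), b = c(4, 0)), NULL, list(K = array(0, c(2, 2))))
  cl <- clip_global_norm(g, 1.0)
  expect_equal(cl$norm, sqrt(9 * 4 + 16))
  total <- sqrt(sum(unlist(cl$grads)^2))
  expect_lte(total, 1 + 1e-6)
  expect_equal(total, 1, tolerance = 1e-12)
  # under the ceiling: untouched
  small <- list(list(W = matrix(0.1, 2, 2)))
  expect_identical(clip_global_norm(small, 1.0)$grads, small)
})

test_that("fit is seed-deterministic and restores the best epoch", {
  set.seed(20)
  d <- phantom_set(16, size = 16L, seed = 500L)
  dat <- list(train = list(x = d$x, y = d$y),
              val = list(x = d$x[1:8, , , , drop = FALSE], y = d$y[1:8]))
  cfg <- train_config(batch_size = 4, max_epochs = 3, base_lr = 1e-3,
                      patience = 3, seed = 13, augment = FALSE)
  set.seed(21); m1 <- build_model(tiny_cfg(n_classes = 4L))
  set.seed(21); m2 <- build_model(tiny_cfg(n_classes = 4L))
  r1 <- fit(m1, dat, cfg)
  r2 <- fit(m2, dat, cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$model$layers, r2$model$layers)
  expect_equal(r1$best_val_accuracy, max(r1$history$val_acc))
  expect_identical(r1$best_epoch,
                   r1$history$epoch[which.max(r1$history$val_acc)])
  # zero learning rate: nothing improves after epoch 0, so patience-p
  # stopping fires after exactly p more epochs
  cfg0 <- train_config(batch_size = 4, max_epochs = 10, base_lr = 0, min_lr = 0,
                       patience = 2, seed = 13, augment = FALSE)
  set.seed(21); m3 <- build_model(tiny_cfg(n_classes = 4L))
  r3 <- fit(m3, dat, cfg0)
  expect_identical(nrow(r3$history), 3L)  # epochs 0, 1, 2
  expect_identical(r3$best_epoch, 0L)
  # best-epoch weights restored: with lr 0 they equal the initial ones
  set.seed(21); m4 <- build_model(tiny_cfg(n_classes = 4L))
  expect_equal(r3$model$layers[[2]]$par$W, m4$layers[[2]]$par$W)
  expect_error(fit(m3, list(train = dat$train, val = list(x = NULL, y = integer(0))), cfg0),
               "val split")
})

test_that("class weighting does not hurt minority recall under 9:1 imbalance", {
  set.seed(80)
  n_maj <- 36; n_min <- 4
  x <- array(0, c(n_maj + n_min, 16, 16, 3)); y <- integer(n_maj + n_min)
  for (i in 1:n_maj) { x[i, , , ] <- make_phantom("glioma", size = 16, seed = 2000 + i); y[i] <- 1 }
  for (i in 1:n_min) { x[n_maj + i, , , ] <- make_phantom("no_tumor", size = 16, seed = 3000 + i); y[n_maj + i] <- 2 }
  xe <- array(0, c(20, 16, 16, 3)); ye <- rep(1:2, each = 10)
  for (i in 1:10) {
    xe[i, , , ] <- make_phantom("glioma", size = 16, seed = 4000 + i)
    xe[10 + i, , , ] <- make_phantom("no_tumor", size = 16, seed = 5000 + i)
  }
  cfg_of <- function(seed, cw)
    train_config(batch_size = 8, max_epochs = 6, base_lr = 3e-3, patience = 6,
                 seed = seed, augment = FALSE, class_weighting = cw,
                 curriculum = list(list(until = Inf,
                   policy = c(p_mixup = 0, p_cutmix = 0, p_erase = 0,
                              p_clahe = 0, eps_ls = 0))))
  tc <- arch_config(input_size = 16L, stem_widths = c(4L, 6L),
                    block_widths = c(8L, 10L, 12L), se_bottleneck = 2L,
                    head_units = 8L, dropout = 0, noise_std = 0,
                    n_classes = 2L, param_target = NULL)
  minority_recall <- function(cw) vapply(1:5, function(s) {
    set.seed(50); m <- build_model(tc)
    r <- fit(m, list(train = list(x = x, y = y), val = list(x = x, y = y)),
             cfg_of(s, cw))
    p <- predict_proba(r$model, xe)
    mean(max.col(p)[ye == 2] == 2)
  }, numeric(1))
  expect_gte(mean(minority_recall(TRUE)), mean(minority_recall(FALSE)))
})
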