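# Architecture: activations, attention gates, parameter accounting,
# capacity padding, and a finite-difference check of the full
# hand-written backward pass.

test_that("GELU matches its closed form", {
  expect_identical(gelu(0), 0)
  expect_equal(gelu(1), 0.8411920, tolerance = 1e-6)
  expect_gt(gelu(-6), -1e-6)
  expect_lt(gelu(-6), 0)
  # gating identity of the tanh form: gelu(z) - gelu(-z) = z
  z <- seq(-3, 3, by = 0.1)
  expect_equal(gelu(z) - gelu(-z), z, tolerance = 1e-12)
})

test_that("SE gate squeezes to channel means and rescales in (0, 1)", {
  set.seed(2)
  U <- array(runif(2 * 4 * 4 * 6), c(2, 4, 4, 6))
  b <- 3L
  # zero weights force s = sigmoid(0) = 0.5
  z0 <- sepattnet:::.se_fw(U, matrix(0, b, 6), rep(0, b), matrix(0, 6, b), rep(0, 6))
  expect_equal(z0$out, U / 2, tolerance = 1e-12)
  expect_equal(sepattnet:::.se_fw(U * 0, matrix(0, b, 6), rep(0, b),
                                  matrix(0, 6, b), rep(0, 6))$out,
               U * 0)
  # squeeze of a constant channel is exactly its value
  Uc <- array(0.37, c(1, 5, 5, 2))
  expect_equal(as.vector(sepattnet:::.se_fw(Uc, matrix(0, 1, 2), 0,
                                            matrix(0, 2, 1), rep(0, 2))$cache$z),
               c(0.37, 0.37))
  # random weights: multiplier strictly inside (0, 1), so |out| <= |U|
  W1 <- matrix(rnorm(b * 6), b, 6); W2 <- matrix(rnorm(6 * b), 6, b)
  r <- sepattnet:::.se_fw(U, W1, rnorm(b), W2, rnorm(6))
  expect_true(all(r$cache$s > 0 & r$cache$s < 1))
  expect_true(all(abs(r$out) <= abs(U)))
})

test_that("spatial gate broadcasts one (0,1) map over channels", {
  set.seed(3)
  U <- array(rnorm(2 * 8 * 8 * 5), c(2, 8, 8, 5))
  z0 <- sepattnet:::.spatial_fw(U, array(0, c(7, 7, 2, 1)), 0)
  expect_equal(z0$out, U / 2, tolerance = 1e-12)
  W7 <- array(rnorm(7 * 7 * 2), c(7, 7, 2, 1))
  r <- sepattnet:::.spatial_fw(U, W7, 0.1)
  expect_true(all(r$cache$S > 0 & r$cache$S < 1))
  # the gate ratio is channel-independent
  ratio <- r$out / U
  expect_equal(ratio[, , , 1], ratio[, , , 5], tolerance = 1e-12)
  expect_true(all(abs(r$out) <= abs(U)))
})

test_that("parameter accounting matches the separable-block formulas", {
  set.seed(4)
  cfg <- arch_config(input_size = 64L, stem_widths = c(8L, 64L),
                     block_widths = c(128L, 160L, 192L), se_bottleneck = 16L,
                     head_units = 16L, n_classes = 4L, param_target = NULL)
  m <- build_model(cfg)
  per <- model_summary(m)$per_layer
  at <- function(nm) per$params[per$name == nm]
  # depthwise 3x3 on C=64: 9C; pointwise 64 -> 128: C*F
  expect_identical(at("sep1_dw"), 9 * 64)
  expect_identical(at("sep1_pw"), 64 * 128)
  expect_identical(at("sep1_bn"), 2 * 128)
  # SE with fixed bottleneck 16 on F channels: F*16 + 16 + 16*F + F
  expect_identical(at("sep1_se"), 128 * 16 + 16 + 16 * 128 + 128)
  expect_identical(at("sep1_sa"), 7 * 7 * 2 + 1)
  # a lone dense layer with bias: in*out + out
  expect_identical(at("classifier"), 16 * 4 + 4)
})

test_that("model forward is a softmax classifier, deterministic at inference", {
  set.seed(5)
  m <- build_model(tiny_cfg(n_classes = 4L))
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  p <- predict_proba(m, x)
  expect_identical(dim(p), c(1L, 4L))
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_identical(predict_proba(m, x), p)
  # zero input stays zero through the conv trunk: uniform softmax head
  p0 <- predict_proba(m, array(0, c(16, 16, 3)))
  expect_equal(sum(p0), 1, tolerance = 1e-6)
})

test_that("default budget is met exactly and padding is forward-inert", {
  set.seed(6)
  full <- build_model(arch_config())
  expect_identical(count_trainables(full), 1461587L)
  s <- model_summary(full)
  expect_identical(s$total_trainable, 1461587L)
  expect_lte(s$base_trainable, 1461587L)
  expect_equal(s$size_bytes / 2^20, 5.6, tolerance = 0.1 / 5.6)

  # padding: exact count, identical outputs, zero gradients
  set.seed(7)
  base <- build_model(tiny_cfg(n_classes = 3L))
  target <- count_trainables(base) + 1000L
  padded <- apply_param_pad(base, target)
  expect_identical(count_trainables(padded), target)
  expect_length(padded$pad, 1000L)
  same <- apply_param_pad(base, count_trainables(base))
  expect_length(same$pad, 0L)
  for (i in 1:10) {
    x <- array(runif(2 * 16 * 16 * 3), c(2, 16, 16, 3))
    expect_identical(predict_proba(padded, x), predict_proba(base, x))
  }
  fw <- sepattnet:::model_forward(padded, x, training = TRUE)
  bw <- sepattnet:::model_backward(padded, fw$caches, fw$probs - fw$probs[, c(2, 3, 1)])
  expect_identical(bw$dpad, numeric(1000L))
  expect_error(apply_param_pad(base, count_trainables(base) - 1L), "budget exceeded")
})

test_that("MAC accounting follows the conv and dense formulas", {
  set.seed(8)
  m <- build_model(arch_config(input_size = 256L, param_target = NULL))
  per <- model_summary(m)$per_layer
  at <- function(nm) per$macs[per$name == nm]
  expect_identical(at("head_dense"), 640 * 256)
  # pointwise 64 -> 128 at 128 x 128 resolution
  expect_identical(at("sep1_pw"), 64 * 128 * 128^2)
  expect_identical(at("sep1_dw"), 9 * 64 * 128^2)
  expect_identical(count_macs(m), sum(per$macs))
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(9)
  m <- build_model(tiny_cfg(n_classes = 3L))
  x <- array(runif(2 * 16 * 16 * 3), c(2, 16, 16, 3))
  y <- rbind(c(1, 0, 0), c(0, 0, 1))
  loss_of <- function(mod) {
    fw <- sepattnet:::model_forward(mod, x, training = TRUE)
    -mean(rowSums(y * log(pmax(fw$probs, 1e-12))))
  }
  fw <- sepattnet:::model_forward(m, x, training = TRUE)
  bw <- sepattnet:::model_backward(m, fw$caches, (fw$probs - y) / 2)
  eps <- 1e-5
  for (li in seq_along(m$layers)) {
    if (is.null(m$layers[[li]]$par)) next
    for (pn in names(m$layers[[li]]$par)) {
      pv <- m$layers[[li]]$par[[pn]]
      for (i in sample(length(pv), min(2, length(pv)))) {
        mp <- m; mp$layers[[li]]$par[[pn]][i] <- pv[i] + eps
        mm <- m; mm$layers[[li]]$par[[pn]][i] <- pv[i] - eps
        num <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
        ana <- bw$grads[[li]][[pn]][i]
        expect_equal(ana, num, tolerance = 5e-3,
                     label = sprintf("grad %s/%s", m$layers[[li]]$name, pn))
      }
    }
  }
})

test_that("checkpoints round-trip to identical forward outputs", {
  set.seed(10)
  m <- build_model(tiny_cfg())
  f <- withr::local_tempfile(fileext = ".ckpt")
  save_model(m, f)
  m2 <- load_model(f)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_identical(predict_proba(m2, x), predict_proba(m, x))
})
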