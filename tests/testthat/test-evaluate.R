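# Evaluation: TTA views, confusion matrix, classification report,
# calibration (ECE, reliability bins) and Brier score.

# model whose output is constant in the input: zero classifier weights
# leave only the bias logits
constant_model <- function(bias = c(0.2, 0.5, 0.1, 0.3)) {
  set.seed(31)
  m <- build_model(tiny_cfg(n_classes = 4L))
  li <- length(m$layers)
  m$layers[[li]]$par$W[] <- 0
  m$layers[[li]]$par$b <- bias
  m
}

test_that("TTA uses exactly five deterministic views and averages them", {
  cfg <- tta_config()
  expect_length(cfg$transforms, 5)
  expect_named(cfg$transforms, c("identity", "hflip", "rot_pos", "rot_neg", "gamma"))
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  # views are deterministic functions
  for (f in cfg$transforms) expect_identical(f(img), f(img))
  # flip view is an involution; identity is identity
  expect_identical(cfg$transforms$identity(img), img)
  expect_equal(cfg$transforms$hflip(cfg$transforms$hflip(img)), img)

  m <- constant_model()
  p1 <- tta_predict(m, img)
  expect_equal(sum(p1), 1, tolerance = 1e-6)
  # constant model: TTA mean equals the single-view output
  expect_equal(p1, predict_proba(m, img)[1, ], tolerance = 1e-12)
  # repeated evaluation is bit-identical
  expect_identical(tta_predict(m, img), p1)
  set.seed(32)
  m2 <- build_model(tiny_cfg(n_classes = 4L))
  expect_identical(tta_predict(m2, img), tta_predict(m2, img))
  expect_equal(sum(tta_predict(m2, img)), 1, tolerance = 1e-6)
})

test_that("confusion matrix counts actual rows against predicted columns", {
  C <- confusion_matrix(c(1, 1, 2), c(1, 2, 2), K = 2)
  expect_identical(C, matrix(c(1L, 0L, 1L, 1L), 2, 2))
  Cp <- confusion_matrix(1:4, 1:4, K = 4)
  expect_identical(Cp, diag(1L, 4L))
  expect_identical(sum(C), 3L)
  expect_error(confusion_matrix(c(1, 5), c(1, 1), K = 4), "out of range")
})

test_that("classification report matches hand-computed metrics", {
  C <- matrix(c(8, 2, 1, 9), 2, 2, byrow = TRUE)
  r <- classification_report(C)
  expect_equal(unname(r$per_class$precision), c(8 / 9, 9 / 11))
  expect_equal(unname(r$per_class$recall), c(0.8, 0.9))
  expect_equal(r$per_class$f1[1], 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8))
  expect_equal(r$per_class$f1[1], 0.8421, tolerance = 1e-4)
  expect_equal(r$accuracy, 17 / 20)
  d <- diag(c(3L, 5L, 2L))
  rd <- classification_report(d)
  expect_equal(unname(rd$macro_avg), rep(1, 3))
  expect_equal(rd$accuracy, 1)
  # weighted-average recall is identically the accuracy
  set.seed(41)
  for (i in 1:25) {
    K <- sample(2:6, 1)
    M <- matrix(rpois(K * K, 5), K, K)
    M <- M + diag(K)  # avoid empty rows
    rr <- classification_report(M)
    expect_equal(unname(rr$weighted_avg["recall"]), rr$accuracy, tolerance = 1e-12)
  }
  # zero-division flagged, not propagated
  z <- classification_report(matrix(c(2, 0, 1, 0), 2, 2, byrow = TRUE))
  expect_true(z$zero_division)
  expect_identical(unname(z$per_class$precision[2]), 0)
})

test_that("ECE agrees with a brute-force per-sample binning oracle", {
  # analytic single-bin case: 10 samples at confidence 0.8, 6 correct
  p <- matrix(c(rep(0.8, 10), rep(0.2 / 3, 30)), 10, 4)
  labels <- c(rep(1L, 6), rep(2L, 4))
  expect_equal(ece(p, labels), 0.2, tolerance = 1e-12)
  # perfect confident predictions
  expect_equal(ece(diag(4)[c(1, 2, 3, 4), ] * 0.999999 + 0.00000025, 1:4), 0,
               tolerance = 1e-5)
  # order invariance
  set.seed(51)
  pr <- rand_probs(200, 4)
  lb <- sample(1:4, 200, replace = TRUE)
  perm <- sample(200)
  expect_equal(ece(pr, lb), ece(pr[perm, ], lb[perm]), tolerance = 1e-15)
  # brute-force oracle: per-sample loop, right-closed equal-width bins
  ece_oracle <- function(probs, labels, n_bins = 10) {
    conf <- apply(probs, 1, max)
    pred <- max.col(probs)
    n <- length(labels)
    tot <- 0
    for (b in seq_len(n_bins)) {
      lo <- (b - 1) / n_bins; hi <- b / n_bins
      inb <- which(if (b == 1) conf <= hi else conf > lo & conf <= hi)
      if (!length(inb)) next
      tot <- tot + length(inb) / n * abs(mean(pred[inb] == labels[inb]) - mean(conf[inb]))
    }
    tot
  }
  for (i in 1:10) {
    pr <- rand_probs(100, sample(2:5, 1))
    lb <- sample(ncol(pr), 100, replace = TRUE)
    expect_equal(ece(pr, lb), ece_oracle(pr, lb), tolerance = 1e-12)
  }
})

test_that("a per-bin calibrated predictor has near-zero ECE", {
  # construct confidences at bin centers with per-bin accuracy equal to
  # the bin's mean confidence
  probs <- NULL; labels <- integer(0)
  for (c in seq(0.55, 0.95, by = 0.1)) {
    m <- 100
    n_correct <- round(c * m)
    p <- matrix(rep(c(c, 1 - c), m), m, 2, byrow = TRUE)
    probs <- rbind(probs, p)
    labels <- c(labels, rep(1L, n_correct), rep(2L, m - n_correct))
  }
  expect_lte(ece(probs, labels), 2 / length(labels))
})

test_that("Brier score matches its analytic cases", {
  expect_equal(brier(diag(4)[1:4, ], 1:4), 0)
  expect_equal(brier(matrix(0.25, 5, 4), rep(2L, 5)), 0.75, tolerance = 1e-12)
  wrong <- matrix(c(1, 0, 0, 0), 1)
  expect_equal(brier(wrong, 2L), 2)
  # bounds on random inputs
  set.seed(61)
  pr <- rand_probs(100, 4)
  b <- brier(pr, sample(1:4, 100, replace = TRUE))
  expect_gte(b, 0); expect_lte(b, 2)
})

test_that("reliability bins conserve counts and stay inside their ranges", {
  set.seed(71)
  pr <- rand_probs(300, 4)
  lb <- sample(1:4, 300, replace = TRUE)
  rb <- reliability_bins(pr, lb)
  expect_identical(sum(rb$count), 300L)
  ok <- rb$count > 0
  expect_true(all(rb$mean_confidence[ok] > rb$bin_lo[ok]))
  expect_true(all(rb$mean_confidence[ok] <= rb$bin_hi[ok]))
  expect_true(all(rb$accuracy[ok] >= 0 & rb$accuracy[ok] <= 1))
})

test_that("evaluate_split assembles a consistent report with or without TTA", {
  d <- phantom_set(12, size = 16L, seed = 700L)
  m <- constant_model()
  ev <- evaluate_split(m, d, tta = TRUE)
  expect_identical(sum(ev$confusion), 12L)
  expect_identical(unname(rowSums(ev$confusion)),
                   unname(ev$report$per_class$support))
  expect_equal(ev$accuracy, sum(diag(ev$confusion)) / 12)
  expect_gte(ev$ece, 0); expect_lte(ev$ece, 1)
  ev2 <- evaluate_split(m, d, tta = FALSE)
  expect_identical(names(ev), names(ev2))
  expect_identical(dim(ev2$probs), dim(ev$probs))
  # writing the report emits the four artifacts
  out <- withr::local_tempdir()
  write_eval_report(ev, out)
  expect_true(all(file.exists(file.path(out,
    c("report.json", "report.csv", "confusion.csv", "reliability.csv")))))
})
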