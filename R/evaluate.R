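# Evaluation: five-view test-time augmentation, confusion matrix,
# per-class precision/recall/F1 with macro and weighted averages,
# expected calibration error, Brier score and reliability bins.

#' Test-time augmentation configuration
#'
#' The default five deterministic views: identity, horizontal flip,
#' rotations of +8 and -8 degrees (bilinear, zero fill), and a mild
#' gamma adjustment `x^gamma`. No RNG is involved, so repeated
#' evaluation is bit-identical.
#'
#' @param rot_deg Rotation magnitude in degrees.
#' @param gamma Gamma exponent for the photometric view.
#' @return List of class `tta_config` with an ordered `transforms`
#'   list of image -> image functions.
#' @export
tta_config <- function(rot_deg = 8, gamma = 0.9) {
  transforms <- list(
    identity = function(img) img,
    hflip = function(img) img[, rev(seq_len(dim(img)[2])), , drop = FALSE],
    rot_pos = function(img) warp_affine(img, rotation_inverse(rot_deg)),
    rot_neg = function(img) warp_affine(img, rotation_inverse(-rot_deg)),
    gamma = function(img) clip01(img)^gamma
  )
  structure(list(transforms = transforms, rot_deg = rot_deg, gamma = gamma),
            class = "tta_config")
}

#' Test-time-augmented prediction for one image
#'
#' Averages the softmax outputs of the model over the deterministic
#' views (one forward pass per view); the mean of simplex points is
#' again a probability vector.
#'
#' @param model A `sepattnet_model` (inference mode is used).
#' @param image Preprocessed `(H, W, C)` image in \[0, 1\] at the
#'   model's input size.
#' @param cfg A [tta_config()].
#' @return Length-K probability vector.
#' @export
tta_predict <- function(model, image, cfg = tta_config()) {
  views <- lapply(cfg$transforms, function(f) f(image))
  n <- length(views)
  d <- dim(image)
  batch <- array(0, c(n, d))
  for (i in seq_len(n)) batch[i, , , ] <- views[[i]]
  colMeans(predict_proba(model, batch))
}

#' Confusion matrix
#'
#' `C[actual, predicted]` counts; row sums are the class supports.
#'
#' @param y_true,y_pred Integer labels in `[1, K]`.
#' @param K Number of classes.
#' @return K x K integer matrix.
#' @export
confusion_matrix <- function(y_true, y_pred, K) {
  if (any(y_true < 1 | y_true > K) || any(y_pred < 1 | y_pred > K))
    stop("labels out of range [1, K]")
  C <- matrix(0L, K, K)
  for (i in seq_along(y_true))
    C[y_true[i], y_pred[i]] <- C[y_true[i], y_pred[i]] + 1L
  C
}

#' Per-class and averaged classification metrics
#'
#' From a confusion matrix with rows = actual: `precision_k =
#' C_kk / colsum_k`, `recall_k = C_kk / rowsum_k`, F1 their harmonic
#' mean; macro averages are unweighted means, weighted averages are
#' support-weighted, and accuracy is `trace / n` (identically the
#' weighted-average recall). Zero-division (empty predicted or actual
#' class) yields 0 and sets the `zero_division` flag.
#'
#' @param C K x K non-negative confusion matrix.
#' @param classes Optional class names.
#' @return List of class `classification_report`: `per_class`
#'   data.frame, `accuracy`, `macro_avg`, `weighted_avg`, `n`,
#'   `zero_division`.
#' @export
classification_report <- function(C, classes = NULL) {
  if (!length(C) || nrow(C) != ncol(C)) stop("confusion matrix must be square and non-empty")
  K <- nrow(C)
  if (is.null(classes)) classes <- rownames(C) %||% paste0("class_", seq_len(K))
  n <- sum(C)
  support <- rowSums(C)
  predicted <- colSums(C)
  diagc <- diag(C)
  zdiv <- any(predicted == 0) || any(support == 0)
  prec <- ifelse(predicted > 0, diagc / predicted, 0)
  rec <- ifelse(support > 0, diagc / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  per <- data.frame(class = classes, precision = prec, recall = rec,
                    f1 = f1, support = support)
  wavg <- function(v) sum(v * support) / n
  structure(list(
    per_class = per,
    accuracy = sum(diagc) / n,
    macro_avg = c(precision = mean(prec), recall = mean(rec), f1 = mean(f1)),
    weighted_avg = c(precision = wavg(prec), recall = wavg(rec), f1 = wavg(f1)),
    n = n, zero_division = zdiv), class = "classification_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.classification_report <- function(x, ...) {
  df <- x$per_class
  df[, 2:4] <- round(df[, 2:4], 4)
  print(df, row.names = FALSE)
  cat(sprintf("accuracy %.4f (n = %d)\n", x$accuracy, x$n))
  cat(sprintf("macro avg    P %.4f R %.4f F1 %.4f\n",
              x$macro_avg[1], x$macro_avg[2], x$macro_avg[3]))
  cat(sprintf("weighted avg P %.4f R %.4f F1 %.4f\n",
              x$weighted_avg[1], x$weighted_avg[2], x$weighted_avg[3]))
  invisible(x)
}

# equal-width right-closed confidence bins; conf = max predicted prob
.bin_index <- function(conf, n_bins) {
  pmin(pmax(ceiling(conf * n_bins), 1L), n_bins)
}

#' Reliability bins
#'
#' Partitions \[0, 1\] into `n_bins` equal-width right-closed bins on
#' the prediction confidence (max probability) and reports per-bin
#' count, mean confidence and empirical accuracy.
#'
#' @param probs N x K probability matrix.
#' @param labels Integer true labels in `[1, K]`.
#' @param n_bins Number of bins (default 10).
#' @return data.frame with `bin_lo`, `bin_hi`, `count`,
#'   `mean_confidence`, `accuracy`.
#' @export
reliability_bins <- function(probs, labels, n_bins = 10L) {
  if (!nrow(probs)) stop("empty input")
  conf <- apply(probs, 1, max)
  correct <- max.col(probs) == labels
  b <- .bin_index(conf, n_bins)
  data.frame(
    bin_lo = (seq_len(n_bins) - 1) / n_bins,
    bin_hi = seq_len(n_bins) / n_bins,
    count = tabulate(b, n_bins),
    mean_confidence = vapply(seq_len(n_bins), function(i)
      if (any(b == i)) mean(conf[b == i]) else NA_real_, numeric(1)),
    accuracy = vapply(seq_len(n_bins), function(i)
      if (any(b == i)) mean(correct[b == i]) else NA_real_, numeric(1)))
}

#' Expected calibration error
#'
#' `ECE = sum_b (n_b / n) * |acc_b - conf_b|` over equal-width
#' right-closed confidence bins.
#'
#' @inheritParams reliability_bins
#' @return ECE in \[0, 1\].
#' @export
ece <- function(probs, labels, n_bins = 10L) {
  rb <- reliability_bins(probs, labels, n_bins)
  ok <- rb$count > 0
  sum(rb$count[ok] / sum(rb$count) * abs(rb$accuracy[ok] - rb$mean_confidence[ok]))
}

#' Multiclass Brier score
#'
#' Full sum-over-classes form `(1/n) * sum_i sum_k (p_ik - y_ik)^2`
#' with one-hot truth; 0 for perfect one-hot predictions, 2 for a
#' maximally confident wrong prediction.
#'
#' @param probs N x K probability matrix.
#' @param labels Integer true labels in `[1, K]`.
#' @return Brier score in \[0, 2\].
#' @export
brier <- function(probs, labels) {
  if (!nrow(probs)) stop("empty input")
  y <- one_hot(labels, ncol(probs))
  mean(rowSums((probs - y)^2))
}

#' Evaluate a model on one manifest split
#'
#' Runs (optionally TTA-averaged) prediction over every record of the
#' split and assembles the full report: confusion matrix, per-class
#' precision/recall/F1 with macro and weighted averages, accuracy, ECE,
#' Brier score and reliability bins. Deterministic given model and
#' split.
#'
#' @param model A trained `sepattnet_model`.
#' @param data In-memory split from [load_split_images()] (or any
#'   `list(x, y)` at the model's input size).
#' @param tta Use the five-view TTA average (default TRUE).
#' @param tta_cfg A [tta_config()].
#' @param n_bins Calibration bin count.
#' @return List of class `eval_report` with `confusion`, `report`,
#'   `accuracy`, `ece`, `brier`, `reliability`, `probs`, `n`.
#' @export
evaluate_split <- function(model, data, tta = TRUE, tta_cfg = tta_config(),
                           n_bins = 10L) {
  n <- length(data$y)
  if (!n) stop("split is empty")
  K <- model$cfg$n_classes
  if (tta) {
    probs <- t(vapply(seq_len(n), function(i)
      tta_predict(model, data$x[i, , , ], tta_cfg), numeric(K)))
  } else {
    probs <- predict_proba(model, data$x)
  }
  pred <- max.col(probs, ties.method = "first")
  C <- confusion_matrix(data$y, pred, K)
  classes <- data$classes %||% paste0("class_", seq_len(K))
  rownames(C) <- colnames(C) <- classes
  structure(list(
    confusion = C,
    report = classification_report(C, classes),
    accuracy = mean(pred == data$y),
    ece = ece(probs, data$y, n_bins),
    brier = brier(probs, data$y),
    reliability = reliability_bins(probs, data$y, n_bins),
    probs = probs, n = n, tta = tta), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Evaluation on", x$n, "images", if (x$tta) "(5-view TTA)" else "(single view)", "\n")
  print(x$report)
  cat(sprintf("ECE %.4f | Brier %.4f\n", x$ece, x$brier))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Emits `report.json` (the full report), `report.csv` (per-class rows
#' plus accuracy / macro avg / weighted avg), `confusion.csv` and
#' `reliability.csv` under `dir`.
#'
#' @param report An `eval_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rep <- report$report
  rows <- rep$per_class
  rows$class <- as.character(rows$class)
  extra <- data.frame(
    class = c("accuracy", "macro avg", "weighted avg"),
    precision = c(NA, rep$macro_avg[1], rep$weighted_avg[1]),
    recall = c(NA, rep$macro_avg[2], rep$weighted_avg[2]),
    f1 = c(rep$accuracy, rep$macro_avg[3], rep$weighted_avg[3]),
    support = c(rep$n, rep$n, rep$n))
  utils::write.csv(rbind(rows, extra), file.path(dir, "report.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$confusion), file.path(dir, "confusion.csv"))
  utils::write.csv(report$reliability, file.path(dir, "reliability.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n = report$n, tta = report$tta, accuracy = report$accuracy,
         ece = report$ece, brier = report$brier,
         confusion = report$confusion, per_class = rows,
         macro_avg = as.list(rep$macro_avg),
         weighted_avg = as.list(rep$weighted_avg),
         reliability = report$reliability),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
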