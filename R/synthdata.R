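# Synthetic phantom brain-MRI generator: renders a skull ellipse with
# textured interior and a class-conditional lesion, and writes full
# corpus trees (class folders, synonym names, injected byte-identical
# duplicates, Training/Testing containers) so the entire pipeline is
# testable without any download. Classes are separable by lesion
# geometry (size, shape, placement), not intensity alone.

# folder names used when synonym_dirs is on (all resolve through the
# canonicalization table)
.SYNONYM_DIRNAMES <- c(glioma = "glioma_tumor", meningioma = "meningioma",
                       no_tumor = "notumor", pituitary = "pituitary_tumor")

#' Render one phantom brain image
#'
#' Draws an elliptical skull rim, smooth tissue texture, an optional
#' class-conditional lesion and seeded additive noise:
#' * `glioma` — a large irregular blob, laterally offset into one
#'   hemisphere, with an angularly modulated boundary;
#' * `meningioma` — a medium disc attached to the inner skull rim at a
#'   random angle;
#' * `pituitary` — a small midline-inferior blob;
#' * `no_tumor` — no lesion.
#' Deterministic per `(label, size, seed)`.
#'
#' @param label Canonical class label.
#' @param size Side length in pixels (default 64).
#' @param noise_level Additive Gaussian noise sd (default 0.02).
#' @param seed Integer seed.
#' @param return_mask Also return the lesion mask.
#' @return `(size, size, 3)` array in \[0, 1\]; with `return_mask`,
#'   a list `list(image, lesion_mask)`.
#' @export
make_phantom <- function(label, size = 64L, noise_level = 0.02, seed = 0L,
                         return_mask = FALSE) {
  if (!label %in% CANONICAL_CLASSES)
    stop("unknown class '", label, "'; expected one of: ",
         paste(CANONICAL_CLASSES, collapse = ", "))
  s <- as.integer(size)
  with_seed(seed, {
    yy <- matrix(rep(seq_len(s), times = s), s, s) / s - 0.5
    xx <- matrix(rep(seq_len(s), each = s), s, s) / s - 0.5
    # per-phantom anatomical variability (head size/placement)
    ry <- stats::runif(1, 0.38, 0.45); rx <- stats::runif(1, 0.32, 0.40)
    oy <- stats::runif(1, -0.02, 0.02); ox <- stats::runif(1, -0.02, 0.02)
    yy <- yy - oy; xx <- xx - ox
    rho <- sqrt((yy / ry)^2 + (xx / rx)^2)
    img <- matrix(0.02, s, s)
    brain <- rho < 0.88
    rim <- rho >= 0.88 & rho < 1
    texture <- resize_bilinear(matrix(stats::runif(64, -1, 1), 8, 8), s, s)
    img[brain] <- 0.35 + 0.12 * texture[brain]
    img[rim] <- 0.85
    mask <- matrix(FALSE, s, s)
    if (label == "glioma") {
      side <- sample(c(-1, 1), 1)
      cy <- stats::runif(1, -0.08, 0.08)
      cx <- side * stats::runif(1, 0.10, 0.16)
      ang <- atan2(yy - cy, xx - cx)
      wobble <- 0.04 * sin(3 * ang + stats::runif(1, 0, 2 * pi)) +
        0.03 * sin(5 * ang + stats::runif(1, 0, 2 * pi))
      r <- sqrt((yy - cy)^2 + (xx - cx)^2)
      mask <- r < (0.15 + wobble) & brain
      img[mask] <- 0.85
    } else if (label == "meningioma") {
      theta <- stats::runif(1, 0, 2 * pi)
      # disc center on the inner rim so the lesion stays skull-attached
      cy <- 0.78 * ry * sin(theta)
      cx <- 0.78 * rx * cos(theta)
      r <- sqrt((yy - cy)^2 + (xx - cx)^2)
      mask <- r < 0.085 & brain
      img[mask] <- 0.9
    } else if (label == "pituitary") {
      cy <- 0.20 + stats::runif(1, -0.02, 0.02)
      cx <- stats::runif(1, -0.02, 0.02)
      r <- sqrt((yy - cy)^2 + (xx - cx)^2)
      mask <- r < 0.045 & brain
      img[mask] <- 0.95
    }
    img <- clip01(img + matrix(stats::rnorm(s * s, 0, noise_level), s, s))
    out <- array(rep(img, 3L), c(s, s, 3L))
    if (return_mask) list(image = out, lesion_mask = mask) else out
  })
}

#' Corpus specification
#'
#' @param n_per_class Unique images per class in `Training/`.
#' @param dup_fraction Fraction of each class duplicated byte-identically
#'   (in \[0, 0.5\]).
#' @param synonym_dirs Use raw synonym folder names (`glioma_tumor`,
#'   `notumor`, ...) instead of canonical ones.
#' @param with_testing Also write a predefined `Testing/` container.
#' @param n_test_per_class Images per class in `Testing/` (default
#'   `ceiling(n_per_class / 4)`).
#' @param size Image side length in pixels.
#' @param noise_level Phantom noise sd.
#' @param seed Integer seed.
#' @return List of class `corpus_spec`.
#' @export
corpus_spec <- function(n_per_class = 50L, dup_fraction = 0.1,
                        synonym_dirs = FALSE, with_testing = FALSE,
                        n_test_per_class = NULL, size = 64L,
                        noise_level = 0.02, seed = 0L) {
  stopifnot(dup_fraction >= 0, dup_fraction <= 0.5, n_per_class >= 1)
  if (is.null(n_test_per_class)) n_test_per_class <- ceiling(n_per_class / 4)
  structure(list(n_per_class = as.integer(n_per_class),
                 dup_fraction = dup_fraction, synonym_dirs = synonym_dirs,
                 with_testing = with_testing,
                 n_test_per_class = as.integer(n_test_per_class),
                 size = as.integer(size), noise_level = noise_level,
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

#' Write a phantom corpus tree
#'
#' Writes `Training/<class>/img_XXXX.png` (and optionally
#' `Testing/<class>/...`), injects `round(dup_fraction * n_per_class)`
#' byte-identical duplicate files per class under distinct names, and
#' records ground truth (true labels and the duplicate list) at
#' `<out>/ground_truth.json` for test assertions. Fully reproducible
#' per seed.
#'
#' @param out Output directory (created; must be writable).
#' @param spec A [corpus_spec()].
#' @return Ground-truth list, invisibly.
#' @export
make_corpus <- function(out, spec = corpus_spec()) {
  ok <- dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out)) stop("cannot create output directory: ", out)
  base_seed <- (spec$seed %% 10000L) * 100000L
  n_dup <- as.integer(round_half_up(spec$dup_fraction * spec$n_per_class))
  truth <- list(classes = CANONICAL_CLASSES, files = list(), duplicates = list())
  write_class <- function(container, cls, k, n, seed_off) {
    dirname <- if (spec$synonym_dirs) .SYNONYM_DIRNAMES[[cls]] else cls
    d <- file.path(out, container, dirname)
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    paths <- character(n)
    seen <- character(0)
    for (i in seq_len(n)) {
      # distinct phantoms must carry distinct aHash keys, otherwise the
      # injected-duplicate ground truth would be ambiguous; re-draw on
      # the rare 8x8-thumbnail collision
      for (attempt in 0:24) {
        img <- make_phantom(cls, size = spec$size, noise_level = spec$noise_level,
                            seed = base_seed + seed_off + k * 1000L + i +
                              attempt * 29989L)
        # hash the 8-bit-quantized image: that is what lands on disk
        img <- round(img * 255) / 255
        key <- compute_ahash(img)$key
        if (!key %in% seen) break
      }
      if (key %in% seen) stop("could not generate a hash-distinct phantom")
      seen <- c(seen, key)
      paths[i] <- file.path(d, sprintf("img_%04d.png", i))
      write_image_png(img, paths[i])
    }
    paths
  }
  for (k in seq_along(CANONICAL_CLASSES)) {
    cls <- CANONICAL_CLASSES[k]
    paths <- write_class("Training", cls, k, spec$n_per_class, 0L)
    dups <- character(0)
    if (n_dup > 0) {
      src <- paths[seq_len(n_dup)]
      # the copy sorts after its source, so visit-order dedup drops it
      dups <- file.path(dirname(src), sprintf("img_%04d_copy.png", seq_len(n_dup)))
      file.copy(src, dups)
    }
    truth$files[[cls]] <- basename(c(paths, dups))
    truth$duplicates[[cls]] <- basename(dups)
    if (spec$with_testing)
      write_class("Testing", cls, k, spec$n_test_per_class, 50000L)
  }
  truth$n_per_class <- spec$n_per_class
  truth$n_duplicates_per_class <- n_dup
  jsonlite::write_json(truth, file.path(out, "ground_truth.json"),
                       auto_unbox = TRUE)
  invisible(truth)
}
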