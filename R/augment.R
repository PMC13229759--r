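# Online augmentation: curriculum-annealed policy, random erasing,
# index-aligned MixUp/CutMix, geometric/photometric jitter.

# epoch-indexed curriculum (half-open intervals [0,2), [2,10), [10,36), [36,Inf)):
# mixing/erasing/CLAHE ramp up mid-training and switch off for the
# consolidation phase; label smoothing anneals 0.05 -> 0.03 -> 0.
.CURRICULUM <- list(
  list(until = 2,   policy = c(p_mixup = 0,    p_cutmix = 0,    p_erase = 0,    p_clahe = 0,    eps_ls = 0.05)),
  list(until = 10,  policy = c(p_mixup = 0.15, p_cutmix = 0.15, p_erase = 0.08, p_clahe = 0.06, eps_ls = 0.05)),
  list(until = 36,  policy = c(p_mixup = 0.25, p_cutmix = 0.25, p_erase = 0.12, p_clahe = 0.08, eps_ls = 0.03)),
  list(until = Inf, policy = c(p_mixup = 0,    p_cutmix = 0,    p_erase = 0,    p_clahe = 0,    eps_ls = 0))
)

#' Augmentation policy active at a given epoch
#'
#' Piecewise-constant curriculum over training epochs: mild smoothing
#' only before epoch 2, moderate mixing/erasing/CLAHE on \[2, 10), the
#' strongest regularization on \[10, 36), and everything off from epoch
#' 36 onward.
#'
#' @param epoch Zero-based epoch index.
#' @param table Optional override: list of `list(until, policy)` entries
#'   with strictly increasing `until` (policy active while
#'   `epoch < until`).
#' @return Named numeric vector `(p_mixup, p_cutmix, p_erase, p_clahe,
#'   eps_ls)`, all in \[0, 1\].
#' @export
#' @examples
#' curriculum_at(5)
#' curriculum_at(40)
curriculum_at <- function(epoch, table = NULL) {
  if (epoch < 0) stop("epoch must be >= 0")
  tab <- if (is.null(table)) .CURRICULUM else table
  for (entry in tab) if (epoch < entry$until) return(entry$policy)
  tab[[length(tab)]]$policy
}

#' Default random-erasing parameters
#'
#' Moderate area/aspect ranges; erased pixels are replaced by uniform
#' noise.
#'
#' @param s_min,s_max Erased-area fraction bounds (of H*W).
#' @param r_min,r_max Aspect-ratio bounds.
#' @return List of class `erase_params`.
#' @export
erase_params <- function(s_min = 0.02, s_max = 0.15, r_min = 0.3, r_max = 3.3) {
  stopifnot(s_min > 0, s_min <= s_max, s_max < 1, r_min > 0, r_min <= r_max)
  structure(list(s_min = s_min, s_max = s_max, r_min = r_min, r_max = r_max),
            class = "erase_params")
}

#' Erase one random rectangle, filling it with uniform noise
#'
#' Samples area `S = u * H * W` with `u ~ Unif(s_min, s_max)` and aspect
#' `r ~ Unif(r_min, r_max)`, giving sides `floor(sqrt(S*r))` by
#' `floor(sqrt(S/r))`. The rectangle is placed uniformly among fully
#' contained positions (clipped to the image only when a side exceeds
#' it); its interior is replaced by U(0,1) noise and all pixels outside
#' are untouched. A degenerate rectangle (side < 1 px) is resampled up
#' to 10 times, then the image is returned unchanged.
#'
#' @param image H x W x C array in \[0, 1\].
#' @param params An [erase_params()] object.
#' @return Augmented image, same shape.
#' @export
random_erase <- function(image, params = erase_params()) {
  d <- dim(image)
  h <- d[1]; w <- d[2]
  for (attempt in 1:10) {
    u <- stats::runif(1, params$s_min, params$s_max)
    r <- stats::runif(1, params$r_min, params$r_max)
    S <- u * h * w
    he <- floor(sqrt(S * r)); we <- floor(sqrt(S / r))
    he <- min(he, h); we <- min(we, w)
    if (he < 1 || we < 1) next
    y0 <- sample.int(h - he + 1L, 1L)
    x0 <- sample.int(w - we + 1L, 1L)
    nch <- if (length(d) == 3L) d[3] else 1L
    noise <- array(stats::runif(he * we * nch), c(he, we, nch))
    if (length(d) == 3L) image[y0:(y0 + he - 1L), x0:(x0 + we - 1L), ] <- noise
    else image[y0:(y0 + he - 1L), x0:(x0 + we - 1L)] <- noise[, , 1L]
    return(image)
  }
  image
}

.check_aligned <- function(a, b) {
  if (!identical(dim(a$x), dim(b$x)) || !identical(dim(a$y), dim(b$y)))
    stop("batch pair is not aligned: shapes differ")
}

#' MixUp two aligned batches
#'
#' Draws one mixing weight `lambda ~ Beta(alpha, alpha)` per batch and
#' forms the convex combinations `lambda * x + (1-lambda) * x'` of both
#' images and label rows.
#'
#' @param a,b Batches: lists with `x` (N x H x W x C array) and `y`
#'   (N x K label matrix, rows summing to 1).
#' @param alpha Beta concentration (default 0.3).
#' @param lambda Optional fixed mixing weight (overrides sampling).
#' @return Mixed batch `list(x, y, lambda)`.
#' @export
mixup_batch <- function(a, b, alpha = 0.3, lambda = NULL) {
  .check_aligned(a, b)
  if (is.null(lambda)) lambda <- stats::rbeta(1, alpha, alpha)
  list(x = lambda * a$x + (1 - lambda) * b$x,
       y = lambda * a$y + (1 - lambda) * b$y,
       lambda = lambda)
}

#' CutMix two aligned batches
#'
#' Pastes one random rectangle of each `b` image into the corresponding
#' `a` image (the same rectangle across the batch) and mixes labels by
#' the retained-area weight `lambda = |M| / (H*W)`, always recomputed
#' from the realized (clipped) rectangle.
#'
#' @param a,b Aligned batches as in [mixup_batch()].
#' @param params Area/aspect law for the rectangle (an [erase_params()];
#'   the same moderate ranges as random erasing).
#' @param rect Optional fixed rectangle `c(y0, x0, he, we)` (1-based
#'   top-left and sides) for deterministic use; sides may be 0.
#' @return Mixed batch `list(x, y, lambda)`.
#' @export
cutmix_batch <- function(a, b, params = erase_params(), rect = NULL) {
  .check_aligned(a, b)
  d <- dim(a$x)
  h <- d[2]; w <- d[3]
  if (is.null(rect)) {
    u <- stats::runif(1, params$s_min, params$s_max)
    r <- stats::runif(1, params$r_min, params$r_max)
    S <- u * h * w
    he <- min(floor(sqrt(S * r)), h); we <- min(floor(sqrt(S / r)), w)
    # center uniform over the image, then clip to bounds
    cy <- sample.int(h, 1L); cx <- sample.int(w, 1L)
    y0 <- max(1L, cy - he %/% 2L); x0 <- max(1L, cx - we %/% 2L)
    he <- min(he, h - y0 + 1L); we <- min(we, w - x0 + 1L)
  } else {
    y0 <- rect[1]; x0 <- rect[2]; he <- rect[3]; we <- rect[4]
  }
  x <- a$x
  if (he >= 1 && we >= 1)
    x[, y0:(y0 + he - 1L), x0:(x0 + we - 1L), ] <-
      b$x[, y0:(y0 + he - 1L), x0:(x0 + we - 1L), ]
  # computed as retained pixels over total so the value is bit-identical
  # to a pixel-count oracle
  lambda <- (h * w - max(he, 0) * max(we, 0)) / (h * w)
  list(x = x, y = lambda * a$y + (1 - lambda) * b$y, lambda = lambda)
}

#' Default geometric/photometric jitter policy
#'
#' @param rot_deg Max absolute rotation (degrees).
#' @param shift_frac Max shift as a fraction of each side.
#' @param shear_deg Max absolute shear (degrees).
#' @param zoom Zoom range (length 2).
#' @param hflip Allow horizontal flips.
#' @param brightness Brightness-scale range (length 2).
#' @return List of class `geom_photo_policy`.
#' @export
geom_photo_policy <- function(rot_deg = 10, shift_frac = 0.08, shear_deg = 6,
                              zoom = c(0.8, 1.2), hflip = TRUE,
                              brightness = c(0.92, 1.10)) {
  structure(list(rot_deg = rot_deg, shift_frac = shift_frac,
                 shear_deg = shear_deg, zoom = zoom, hflip = hflip,
                 brightness = brightness),
            class = "geom_photo_policy")
}

#' Random geometric + photometric augmentation of one image
#'
#' Samples a rotation, shear, zoom and shift within the policy ranges,
#' composes them into a single center-anchored affine warp (bilinear,
#' zero fill), optionally flips horizontally, and scales brightness.
#' Collapsing all ranges to their identity values returns the input
#' unchanged.
#'
#' @param image H x W x C array in \[0, 1\].
#' @param policy A [geom_photo_policy()].
#' @return Augmented image, same shape, clipped to \[0, 1\].
#' @export
geometric_photometric <- function(image, policy = geom_photo_policy()) {
  d <- dim(image)
  h <- d[1]; w <- d[2]
  rot <- stats::runif(1, -policy$rot_deg, policy$rot_deg)
  shear <- stats::runif(1, -policy$shear_deg, policy$shear_deg)
  zoom <- stats::runif(1, policy$zoom[1], policy$zoom[2])
  dy <- stats::runif(1, -policy$shift_frac, policy$shift_frac) * h
  dx <- stats::runif(1, -policy$shift_frac, policy$shift_frac) * w
  flip <- policy$hflip && stats::runif(1) < 0.5
  bright <- stats::runif(1, policy$brightness[1], policy$brightness[2])
  need_warp <- abs(rot) > 0 || abs(shear) > 0 || zoom != 1 || dy != 0 || dx != 0
  if (need_warp) {
    sh <- tan(shear * pi / 180)
    # inverse map: rotate, shear (x by y), then un-zoom
    A <- rotation_inverse(rot) %*% matrix(c(1, 0, sh, 1), 2, 2, byrow = TRUE) / zoom
    image <- warp_affine(image, A, t = c(-dy, -dx))
  }
  if (flip) image <- image[, rev(seq_len(w)), , drop = FALSE]
  clip01(image * bright)
}

#' Stream of index-aligned batch pairs for one epoch
#'
#' Builds two independently seeded permutations of the dataset indices
#' and cuts both into consecutive batches of exactly `batch_size`
#' (the tail that does not fill a batch is dropped). Pairing by position
#' guarantees equal batch sizes without re-shuffling.
#'
#' @param n Dataset size.
#' @param batch_size Batch size (>= 1).
#' @param seed Integer seed; the pair sequence is a pure function of
#'   `(n, batch_size, seed)`.
#' @return List of `list(i, j)` index-vector pairs.
#' @export
paired_batches <- function(n, batch_size, seed) {
  if (n < 1) stop("empty dataset")
  stopifnot(batch_size >= 1)
  n_batches <- n %/% batch_size
  if (n_batches < 1) stop("dataset smaller than one batch")
  p1 <- with_seed(seed * 2L + 1L, sample.int(n))
  p2 <- with_seed(seed * 2L + 2L, sample.int(n))
  lapply(seq_len(n_batches), function(b) {
    idx <- ((b - 1L) * batch_size + 1L):(b * batch_size)
    list(i = p1[idx], j = p2[idx])
  })
}
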