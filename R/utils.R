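# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded internals do not
#' perturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# round-half-up, unlike base round() which rounds half to even
round_half_up <- function(x) floor(x + 0.5)

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Read an image file as an H x W x 3 array in [0, 1]
#'
#' Decodes PNG/JPEG/TIFF via EBImage, converts grayscale to 3 replicated
#' channels and drops any alpha channel.
#'
#' @param path File path.
#' @return Numeric array of dimension `c(H, W, 3)` with values in \[0, 1\].
#' @export
read_image <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  # EBImage stores (x = width, y = height); transpose to row-major H x W
  if (length(dim(a)) == 2L) {
    a <- t(a)
    a <- array(rep(a, 3L), c(dim(a), 3L))
  } else {
    a <- aperm(a, c(2L, 1L, 3L))
    if (dim(a)[3] >= 3L) a <- a[, , 1:3, drop = FALSE]
    else a <- array(rep(a[, , 1L], 3L), c(dim(a)[1:2], 3L))
  }
  clip01(a)
}

#' Write an \[0,1\] image array as PNG
#'
#' @param img H x W (grayscale) or H x W x 3 array in \[0, 1\].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(clip01(img), path)
  invisible(path)
}

# Luma per ITU-R BT.601; used for hashing thumbnails
rgb_to_gray <- function(img) {
  if (length(dim(img)) == 2L) return(img)
  0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
}

#' Bilinear image resize
#'
#' Samples output pixel centers through the usual half-pixel convention
#' (no corner alignment), clamping coordinates at the borders. Applied
#' channel-wise for 3D arrays.
#'
#' @param img H x W or H x W x C numeric array.
#' @param out_h,out_w Output dimensions in pixels.
#' @return Resized array.
#' @export
resize_bilinear <- function(img, out_h, out_w) {
  d <- dim(img)
  if (length(d) == 3L) {
    out <- array(0, c(out_h, out_w, d[3]))
    for (c in seq_len(d[3])) out[, , c] <- resize_bilinear(img[, , c], out_h, out_w)
    return(out)
  }
  h <- d[1]; w <- d[2]
  if (h == out_h && w == out_w) return(img)
  sy <- (seq_len(out_h) - 0.5) * h / out_h - 0.5
  sx <- (seq_len(out_w) - 0.5) * w / out_w - 0.5
  y0 <- pmin(pmax(floor(sy), 0), h - 1); y1 <- pmin(y0 + 1, h - 1)
  x0 <- pmin(pmax(floor(sx), 0), w - 1); x1 <- pmin(x0 + 1, w - 1)
  fy <- pmin(pmax(sy - y0, 0), 1); fx <- pmin(pmax(sx - x0, 0), 1)
  i0 <- y0 + 1L; i1 <- y1 + 1L; j0 <- x0 + 1L; j1 <- x1 + 1L
  top <- img[i0, j0, drop = FALSE] * outer(1 - fy, 1 - fx) +
    img[i0, j1, drop = FALSE] * outer(1 - fy, fx)
  bot <- img[i1, j0, drop = FALSE] * outer(fy, 1 - fx) +
    img[i1, j1, drop = FALSE] * outer(fy, fx)
  top + bot
}

#' Affine warp with bilinear sampling and zero fill
#'
#' Inverse-maps output pixel coordinates through `A` about the image
#' center (plus translation `t`, in pixels) and samples the input
#' bilinearly; coordinates falling outside the input are filled with 0.
#'
#' @param img H x W or H x W x C array.
#' @param A 2 x 2 matrix mapping output-centered coords to input-centered
#'   coords (inverse transform).
#' @param t Length-2 translation (rows, cols) added after `A`.
#' @return Warped array, same shape as `img`.
#' @export
warp_affine <- function(img, A, t = c(0, 0)) {
  d <- dim(img)
  h <- d[1]; w <- d[2]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  gy <- rep(seq_len(h), times = w) - cy
  gx <- rep(seq_len(w), each = h) - cx
  sy <- A[1, 1] * gy + A[1, 2] * gx + cy + t[1]
  sx <- A[2, 1] * gy + A[2, 2] * gx + cx + t[2]
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  sample_ch <- function(ch) {
    val <- function(yy, xx) {
      ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
      v <- numeric(length(yy))
      v[ok] <- ch[cbind(yy[ok], xx[ok])]
      v
    }
    v <- val(y0, x0) * (1 - fy) * (1 - fx) +
      val(y0, x0 + 1) * (1 - fy) * fx +
      val(y0 + 1, x0) * fy * (1 - fx) +
      val(y0 + 1, x0 + 1) * fy * fx
    matrix(v, h, w)
  }
  if (length(d) == 2L) return(sample_ch(img))
  out <- array(0, d)
  for (c in seq_len(d[3])) out[, , c] <- sample_ch(img[, , c])
  out
}

# rotation matrix (degrees, counter-clockwise) for inverse mapping
rotation_inverse <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
}
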