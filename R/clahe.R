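# Contrast-limited adaptive histogram equalization (classic tile-based
# algorithm: per-tile clipped histograms, midpoint-CDF mappings,
# bilinear interpolation between tile centers). The midpoint-CDF
# mapping makes a constant image a fixed point up to quantization.

#' CLAHE on a single grayscale channel
#'
#' @param x H x W matrix in \[0, 1\].
#' @param nx,ny Tile grid (default 8 x 8).
#' @param bins Histogram bins (default 256).
#' @param limit Clip limit as a multiple of the uniform bin height
#'   (default 2).
#' @return Equalized H x W matrix in \[0, 1\].
#' @export
clahe_gray <- function(x, nx = 8L, ny = 8L, bins = 256L, limit = 2) {
  h <- nrow(x); w <- ncol(x)
  nx <- min(nx, w); ny <- min(ny, h)
  # tile boundaries (as equal as possible)
  ybreaks <- floor(seq(0, h, length.out = ny + 1))
  xbreaks <- floor(seq(0, w, length.out = nx + 1))
  bin_of <- function(v) pmin(bins - 1L, as.integer(floor(v * bins)))  # 0-based
  # per-tile mapping LUTs: bins x ny x nx
  luts <- array(0, c(bins, ny, nx))
  ycent <- numeric(ny); xcent <- numeric(nx)
  for (ty in seq_len(ny)) {
    for (tx in seq_len(nx)) {
      rows <- (ybreaks[ty] + 1):ybreaks[ty + 1]
      cols <- (xbreaks[tx] + 1):xbreaks[tx + 1]
      tile <- x[rows, cols]
      npix <- length(tile)
      hist <- tabulate(bin_of(tile) + 1L, nbins = bins)
      climit <- max(1, limit * npix / bins)
      excess <- sum(pmax(hist - climit, 0))
      hist <- pmin(hist, climit) + excess / bins
      cdf <- cumsum(hist)
      # midpoint CDF: unbiased for in-bin placement
      luts[, ty, tx] <- (cdf - hist / 2) / npix
      ycent[ty] <- (ybreaks[ty] + ybreaks[ty + 1] + 1) / 2
      xcent[tx] <- (xbreaks[tx] + xbreaks[tx + 1] + 1) / 2
    }
  }
  # bilinear interpolation of the tile mappings at every pixel
  py <- seq_len(h); px <- seq_len(w)
  ty0 <- pmin(pmax(findInterval(py, ycent), 1L), ny - 1L)
  tx0 <- pmin(pmax(findInterval(px, xcent), 1L), nx - 1L)
  if (ny == 1L) ty0 <- rep(1L, h)
  if (nx == 1L) tx0 <- rep(1L, w)
  fy <- if (ny > 1) pmin(pmax((py - ycent[ty0]) / (ycent[ty0 + 1L] - ycent[ty0]), 0), 1) else rep(0, h)
  fx <- if (nx > 1) pmin(pmax((px - xcent[tx0]) / (xcent[tx0 + 1L] - xcent[tx0]), 0), 1) else rep(0, w)
  b <- matrix(bin_of(x) + 1L, h, w)
  lut_at <- function(ty, tx) {
    # value of tile (ty, tx) mapping at every pixel's bin
    m <- luts[, , , drop = FALSE]
    idx <- b + (ty[row(b)] - 1L) * bins + (tx[col(b)] - 1L) * bins * ny
    matrix(luts[idx], h, w)
  }
  ty1 <- if (ny > 1) ty0 + 1L else ty0
  tx1 <- if (nx > 1) tx0 + 1L else tx0
  Fy <- matrix(fy, h, w); Fx <- matrix(fx, h, w, byrow = TRUE)
  out <- lut_at(ty0, tx0) * (1 - Fy) * (1 - Fx) +
    lut_at(ty0, tx1) * (1 - Fy) * Fx +
    lut_at(ty1, tx0) * Fy * (1 - Fx) +
    lut_at(ty1, tx1) * Fy * Fx
  clip01(out)
}

#' CLAHE on the lightness channel of an RGB image
#'
#' Converts sRGB to CIE-LAB, equalizes the L channel only with
#' [clahe_gray()], converts back and clips to \[0, 1\]. Chroma is left
#' untouched, so local contrast is enhanced without hue shifts.
#'
#' @param image H x W x 3 array in \[0, 1\].
#' @param clip Clip limit (default 2).
#' @param tiles Tile grid side (default 8).
#' @return Equalized image, same shape, values in \[0, 1\].
#' @export
apply_clahe <- function(image, clip = 2, tiles = 8L) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L)
    stop("apply_clahe expects an H x W x 3 image (replicate grayscale upstream)")
  m <- matrix(image, d[1] * d[2], 3L)
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  L <- matrix(lab[, 1] / 100, d[1], d[2])
  Lp <- clahe_gray(L, nx = tiles, ny = tiles, limit = clip)
  lab[, 1] <- as.vector(Lp) * 100
  rgb <- grDevices::convertColor(lab, from = "Lab", to = "sRGB")
  array(clip01(rgb), d)
}
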