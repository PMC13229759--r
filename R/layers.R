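# Layer primitives with hand-written forward and backward passes.
# Batches are arrays of dimension (N, H, W, C); flattening to an
# (N*H*W) x C matrix is a pure dim<- change in column-major order, so
# all channel-wise algebra runs through BLAS. Gradients of every layer
# are checked against central finite differences in the test suite.

.as_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(prod(d[1:3]), d[4])
  x
}

.pad_spatial <- function(x, p) {
  d <- dim(x)
  if (p == 0L) return(x)
  xp <- array(0, c(d[1], d[2] + 2 * p, d[3] + 2 * p, d[4]))
  xp[, p + seq_len(d[2]), p + seq_len(d[3]), ] <- x
  xp
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Gaussian Error Linear Unit (tanh approximation)
#'
#' `0.5 * z * (1 + tanh(sqrt(2/pi) * (z + 0.044715 * z^3)))`, applied
#' elementwise.
#'
#' @param z Numeric vector/array.
#' @return Activated values, same shape.
#' @export
#' @examples
#' gelu(0)
#' gelu(1)
gelu <- function(z) {
  0.5 * z * (1 + tanh(sqrt(2 / pi) * (z + 0.044715 * z^3)))
}

.gelu_grad <- function(z) {
  k <- sqrt(2 / pi)
  u <- k * (z + 0.044715 * z^3)
  t <- tanh(u)
  0.5 * (1 + t) + 0.5 * z * (1 - t^2) * k * (1 + 3 * 0.044715 * z^2)
}

# ---- standard convolution (no bias; same padding) ----

.conv_fw <- function(x, W) {
  d <- dim(x); N <- d[1]; H <- d[2]; Wd <- d[3]; C <- d[4]
  k <- dim(W)[1]; p <- (k - 1L) %/% 2L; Fo <- dim(W)[4]
  xp <- .pad_spatial(x, p)
  outm <- matrix(0, N * H * Wd, Fo)
  for (dy in 0:(k - 1)) for (dx in 0:(k - 1)) {
    Z <- xp[, dy + seq_len(H), dx + seq_len(Wd), , drop = FALSE]
    dim(Z) <- c(N * H * Wd, C)
    outm <- outm + Z %*% matrix(W[dy + 1, dx + 1, , ], C, Fo)
  }
  dim(outm) <- c(N, H, Wd, Fo)
  list(out = outm, xp = xp)
}

.conv_bw <- function(cache, W, dout) {
  xp <- cache$xp
  dp <- dim(xp); N <- dp[1]; C <- dp[4]
  k <- dim(W)[1]; p <- (k - 1L) %/% 2L
  H <- dp[2] - 2 * p; Wd <- dp[3] - 2 * p
  Fo <- dim(W)[4]
  doutm <- dout; dim(doutm) <- c(N * H * Wd, Fo)
  dW <- array(0, dim(W))
  dxp <- array(0, dp)
  for (dy in 0:(k - 1)) for (dx in 0:(k - 1)) {
    Z <- xp[, dy + seq_len(H), dx + seq_len(Wd), , drop = FALSE]
    dim(Z) <- c(N * H * Wd, C)
    dW[dy + 1, dx + 1, , ] <- crossprod(Z, doutm)
    dZ <- doutm %*% t(matrix(W[dy + 1, dx + 1, , ], C, Fo))
    dim(dZ) <- c(N, H, Wd, C)
    dxp[, dy + seq_len(H), dx + seq_len(Wd), ] <-
      dxp[, dy + seq_len(H), dx + seq_len(Wd), , drop = FALSE] + dZ
  }
  dx <- dxp[, p + seq_len(H), p + seq_len(Wd), , drop = FALSE]
  list(dx = dx, dW = dW)
}

# ---- depthwise 3x3 convolution (no bias; same padding) ----

.dwconv_fw <- function(x, K) {
  d <- dim(x); N <- d[1]; H <- d[2]; Wd <- d[3]; C <- d[4]
  k <- dim(K)[1]; p <- (k - 1L) %/% 2L
  xp <- .pad_spatial(x, p)
  n <- N * H * Wd
  outm <- matrix(0, n, C)
  for (dy in 0:(k - 1)) for (dx in 0:(k - 1)) {
    Z <- xp[, dy + seq_len(H), dx + seq_len(Wd), , drop = FALSE]
    dim(Z) <- c(n, C)
    outm <- outm + Z * rep(K[dy + 1, dx + 1, ], each = n)
  }
  dim(outm) <- c(N, H, Wd, C)
  list(out = outm, xp = xp)
}

.dwconv_bw <- function(cache, K, dout) {
  xp <- cache$xp
  dp <- dim(xp); N <- dp[1]; C <- dp[4]
  k <- dim(K)[1]; p <- (k - 1L) %/% 2L
  H <- dp[2] - 2 * p; Wd <- dp[3] - 2 * p
  n <- N * H * Wd
  doutm <- dout; dim(doutm) <- c(n, C)
  dK <- array(0, dim(K))
  dxp <- array(0, dp)
  for (dy in 0:(k - 1)) for (dx in 0:(k - 1)) {
    Z <- xp[, dy + seq_len(H), dx + seq_len(Wd), , drop = FALSE]
    dim(Z) <- c(n, C)
    dK[dy + 1, dx + 1, ] <- colSums(Z * doutm)
    dZ <- doutm * rep(K[dy + 1, dx + 1, ], each = n)
    dim(dZ) <- c(N, H, Wd, C)
    dxp[, dy + seq_len(H), dx + seq_len(Wd), ] <-
      dxp[, dy + seq_len(H), dx + seq_len(Wd), , drop = FALSE] + dZ
  }
  list(dx = dxp[, p + seq_len(H), p + seq_len(Wd), , drop = FALSE], dK = dK)
}

# ---- batch normalization over (N, H, W) per channel ----

.bn_fw <- function(x, gamma, beta, running, training, momentum = 0.9, eps = 1e-5) {
  d <- dim(x)
  m <- .as_mat(x)
  n <- nrow(m)
  if (training) {
    mu <- colMeans(m)
    xc <- m - rep(mu, each = n)
    v <- colMeans(xc * xc)
    running$mean <- momentum * running$mean + (1 - momentum) * mu
    running$var <- momentum * running$var + (1 - momentum) * v * n / max(n - 1, 1)
  } else {
    mu <- running$mean
    v <- running$var
    xc <- m - rep(mu, each = n)
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * rep(inv, each = n)
  out <- xhat * rep(gamma, each = n) + rep(beta, each = n)
  dim(out) <- d
  list(out = out, cache = list(xhat = xhat, inv = inv, d = d), running = running)
}

.bn_bw <- function(cache, gamma, dout) {
  xhat <- cache$xhat; inv <- cache$inv; d <- cache$d
  n <- nrow(xhat)
  dm <- dout; dim(dm) <- dim(xhat)
  dgamma <- colSums(dm * xhat)
  dbeta <- colSums(dm)
  dxhat <- dm * rep(gamma, each = n)
  dx <- (dxhat - rep(colMeans(dxhat), each = n) -
           xhat * rep(colMeans(dxhat * xhat), each = n)) * rep(inv, each = n)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- 2x2 max pooling, stride 2 ----

.maxpool_fw <- function(x) {
  d <- dim(x); H <- d[2]; Wd <- d[3]
  s1 <- seq(1, H, 2); s2 <- seq(2, H, 2)
  t1 <- seq(1, Wd, 2); t2 <- seq(2, Wd, 2)
  a1 <- x[, s1, t1, , drop = FALSE]; a2 <- x[, s1, t2, , drop = FALSE]
  a3 <- x[, s2, t1, , drop = FALSE]; a4 <- x[, s2, t2, , drop = FALSE]
  m <- pmax(a1, a2, a3, a4)
  c1 <- a1 == m
  c2 <- (a2 == m) & !c1
  c3 <- (a3 == m) & !c1 & !c2
  c4 <- !c1 & !c2 & !c3
  list(out = m, cache = list(d = d, c1 = c1, c2 = c2, c3 = c3, c4 = c4))
}

.maxpool_bw <- function(cache, dout) {
  d <- cache$d; H <- d[2]; Wd <- d[3]
  s1 <- seq(1, H, 2); s2 <- seq(2, H, 2)
  t1 <- seq(1, Wd, 2); t2 <- seq(2, Wd, 2)
  dx <- array(0, d)
  dx[, s1, t1, ] <- dout * cache$c1
  dx[, s1, t2, ] <- dout * cache$c2
  dx[, s2, t1, ] <- dout * cache$c3
  dx[, s2, t2, ] <- dout * cache$c4
  dx
}

# ---- channel mean over spatial positions: (N,H,W,C) -> (N,C) ----

.spatial_mean <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1], d[2] * d[3], d[4])
  z <- colSums(aperm(x, c(2, 1, 3))) / (d[2] * d[3])
  dim(z) <- c(d[1], d[4])
  z
}

# broadcast an (N,C) matrix over HW spatial positions -> (N*H*W, C) matrix
.broadcast_nc <- function(z, hw) {
  z[rep(seq_len(nrow(z)), hw), , drop = FALSE]
}

# ---- squeeze-and-excitation channel gate ----

.se_fw <- function(x, W1, b1, W2, b2) {
  d <- dim(x)
  hw <- d[2] * d[3]
  m <- .as_mat(x)
  z <- .spatial_mean(x)
  h1 <- z %*% t(W1) + rep(b1, each = d[1])
  h1 <- pmax(h1, 0)
  s <- .sigmoid(h1 %*% t(W2) + rep(b2, each = d[1]))
  sbig <- .broadcast_nc(s, hw)
  out <- m * sbig
  dim(out) <- d
  list(out = out, cache = list(m = m, z = z, h1 = h1, s = s, sbig = sbig, d = d))
}

.se_bw <- function(cache, W1, W2, dout) {
  d <- cache$d; N <- d[1]; hw <- d[2] * d[3]
  dm <- dout; dim(dm) <- dim(cache$m)
  dx1 <- dm * cache$sbig
  prod_ <- dm * cache$m
  dim(prod_) <- c(N, hw, d[4])
  ds <- colSums(aperm(prod_, c(2, 1, 3)))
  dim(ds) <- c(N, d[4])
  dpre2 <- ds * cache$s * (1 - cache$s)
  dW2 <- crossprod(dpre2, cache$h1)
  db2 <- colSums(dpre2)
  dh1 <- (dpre2 %*% W2) * (cache$h1 > 0)
  dW1 <- crossprod(dh1, cache$z)
  db1 <- colSums(dh1)
  dz <- dh1 %*% W1
  dx <- dx1 + .broadcast_nc(dz, hw) / hw
  dim(dx) <- d
  list(dx = dx, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

# ---- CBAM-style spatial gate ----

.spatial_fw <- function(x, W7, b7) {
  d <- dim(x); N <- d[1]; H <- d[2]; Wd <- d[3]; C <- d[4]
  n <- N * H * Wd
  m <- .as_mat(x)
  mavg <- rowMeans(m)
  mmax <- m[, 1]
  wh <- rep(1L, n)
  if (C > 1) for (c in 2:C) {
    upd <- m[, c] > mmax
    mmax[upd] <- m[upd, c]
    wh[upd] <- c
  }
  stack <- array(c(mavg, mmax), c(N, H, Wd, 2))
  cv <- .conv_fw(stack, W7)
  logits <- cv$out + b7
  S <- .sigmoid(as.vector(logits))
  out <- m * S
  dim(out) <- d
  list(out = out,
       cache = list(m = m, S = S, wh = wh, conv = cv, d = d))
}

.spatial_bw <- function(cache, W7, dout) {
  d <- cache$d; N <- d[1]; H <- d[2]; Wd <- d[3]; C <- d[4]
  n <- N * H * Wd
  dm <- dout; dim(dm) <- c(n, C)
  dx1 <- dm * cache$S
  dS <- rowSums(dm * cache$m)
  dlogits <- dS * cache$S * (1 - cache$S)
  db7 <- sum(dlogits)
  dim(dlogits) <- c(N, H, Wd, 1)
  cb <- .conv_bw(cache$conv, W7, dlogits)
  dstack <- cb$dx
  dmavg <- as.vector(dstack[, , , 1])
  dmmax <- as.vector(dstack[, , , 2])
  dx2 <- matrix(dmavg / C, n, C)
  dx2[cbind(seq_len(n), cache$wh)] <- dx2[cbind(seq_len(n), cache$wh)] + dmmax
  dx <- dx1 + dx2
  dim(dx) <- d
  list(dx = dx, dW = cb$dW, db = db7)
}

# ---- global average pooling and dense ----

.gap_fw <- function(x) {
  d <- dim(x)
  list(out = .spatial_mean(x), cache = d)
}

.gap_bw <- function(cache, dout) {
  d <- cache
  hw <- d[2] * d[3]
  dx <- .broadcast_nc(dout, hw) / hw
  dim(dx) <- d
  dx
}

.dense_fw <- function(x, W, b) {
  list(out = x %*% W + rep(b, each = nrow(x)), cache = x)
}

.dense_bw <- function(cache, W, dout) {
  list(dx = dout %*% t(W), dW = crossprod(cache, dout), db = colSums(dout))
}

.softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}
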