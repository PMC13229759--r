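# Minimal SHA-1 over raw vectors, used to digest 64-bit average-hash
# fingerprints into portable hex keys. Arithmetic is done on doubles
# modulo 2^32 (exact up to 2^53), bit logic through 32-bit integers.

.u32 <- function(x) x %% 4294967296

# bit logic on 16-bit halves (doubles in [0, 2^32) never fit R integers)
.bitop2 <- function(a, b, op) {
  a <- .u32(a); b <- .u32(b)
  ah <- as.integer(a %/% 65536); al <- as.integer(a %% 65536)
  bh <- as.integer(b %/% 65536); bl <- as.integer(b %% 65536)
  as.numeric(op(ah, bh)) * 65536 + as.numeric(op(al, bl))
}

.band <- function(a, b) .bitop2(a, b, bitwAnd)
.bor  <- function(a, b) .bitop2(a, b, bitwOr)
.bxor <- function(a, b) .bitop2(a, b, bitwXor)
.bnot <- function(a) 4294967295 - .u32(a)

.rotl <- function(x, s) {
  x <- .u32(x)
  .u32(x * 2^s) + floor(x / 2^(32 - s))
}

#' SHA-1 digest of a raw vector
#'
#' Standard FIPS 180-1 SHA-1; returns the 40-character lowercase hex
#' digest. Used internally to turn packed average-hash bits into
#' dedup keys, and exported so keys can be recomputed externally.
#'
#' @param bytes Raw vector (any length).
#' @return 40-character hex string.
#' @export
#' @examples
#' sha1_hex(as.raw(rep(0, 8)))
sha1_hex <- function(bytes) {
  stopifnot(is.raw(bytes))
  n <- length(bytes)
  # pad: 0x80, zeros, 64-bit big-endian bit length
  bitlen <- n * 8
  padlen <- (55 - n) %% 64
  msg <- c(bytes, as.raw(0x80), as.raw(rep(0, padlen)),
           as.raw(c(floor(bitlen / 2^56) %% 256, floor(bitlen / 2^48) %% 256,
                    floor(bitlen / 2^40) %% 256, floor(bitlen / 2^32) %% 256,
                    floor(bitlen / 2^24) %% 256, floor(bitlen / 2^16) %% 256,
                    floor(bitlen / 2^8) %% 256, bitlen %% 256)))
  h <- c(1732584193, 4023233417, 2562383102, 271733878, 3285377520)
  m <- as.numeric(msg)
  for (blk in seq_len(length(m) / 64)) {
    off <- (blk - 1) * 64
    w <- numeric(80)
    for (i in 1:16) {
      j <- off + (i - 1) * 4
      w[i] <- m[j + 1] * 16777216 + m[j + 2] * 65536 + m[j + 3] * 256 + m[j + 4]
    }
    for (i in 17:80) w[i] <- .rotl(.bxor(.bxor(w[i - 3], w[i - 8]), .bxor(w[i - 14], w[i - 16])), 1)
    a <- h[1]; b <- h[2]; c <- h[3]; d <- h[4]; e <- h[5]
    for (i in 1:80) {
      if (i <= 20) { f <- .bor(.band(b, c), .band(.bnot(b), d)); k <- 1518500249 }
      else if (i <= 40) { f <- .bxor(.bxor(b, c), d); k <- 1859775393 }
      else if (i <= 60) { f <- .bor(.bor(.band(b, c), .band(b, d)), .band(c, d)); k <- 2400959708 }
      else { f <- .bxor(.bxor(b, c), d); k <- 3395469782 }
      tmp <- .u32(.rotl(a, 5) + f + e + k + w[i])
      e <- d; d <- c; c <- .rotl(b, 30); b <- a; a <- tmp
    }
    h <- .u32(h + c(a, b, c, d, e))
  }
  paste0(vapply(h, function(x)
    sprintf("%04x%04x", as.integer(x %/% 65536), as.integer(x %% 65536)),
    character(1)), collapse = "")
}
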