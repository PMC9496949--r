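# Periodic decimated Daubechies-2 wavelet transform, vectorized across the
# rows of a matrix. Written in-package: motion-artifact correction needs a
# DWT and thresholded reconstruction over arbitrary-length series.

db2_filters <- function() {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))   # scaling
  g <- rev(h) * c(1, -1, 1, -1)                            # wavelet (QMF)
  list(h = h, g = g)
}

# One analysis level. x: rows x N (N even). Returns list(a, d), rows x N/2.
dwt_step <- function(x) {
  f <- db2_filters()
  n <- ncol(x)
  k <- seq(0, n / 2 - 1)
  a <- 0; d <- 0
  for (m in 0:3) {
    idx <- ((2 * k + m) %% n) + 1
    a <- a + f$h[m + 1] * x[, idx, drop = FALSE]
    d <- d + f$g[m + 1] * x[, idx, drop = FALSE]
  }
  list(a = a, d = d)
}

# One synthesis level: exact inverse of dwt_step for even N.
idwt_step <- function(a, d) {
  f <- db2_filters()
  n <- 2 * ncol(a)
  x <- matrix(0, nrow(a), n)
  k <- seq(0, ncol(a) - 1)
  for (m in 0:3) {
    idx <- ((2 * k + m) %% n) + 1
    x[, idx] <- x[, idx] + f$h[m + 1] * a + f$g[m + 1] * d
  }
  x
}

# Full periodic DWT to `levels` levels; N must be divisible by 2^levels.
dwt_periodic <- function(x, levels) {
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- dwt_step(a)
    details[[j]] <- s$d
    a <- s$a
  }
  list(approx = a, details = details)
}

idwt_periodic <- function(decomp) {
  a <- decomp$approx
  for (j in rev(seq_along(decomp$details)))
    a <- idwt_step(a, decomp$details[[j]])
  a
}

# Pad rows symmetrically (reflection) so ncol is a multiple of 2^levels.
reflect_pad <- function(x, multiple) {
  n <- ncol(x)
  target <- ceiling(n / multiple) * multiple
  pad <- target - n
  if (pad == 0) return(x)
  stopifnot(pad < n)
  take <- seq(n, by = -1, length.out = pad)
  cbind(x, x[, take, drop = FALSE])
}
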