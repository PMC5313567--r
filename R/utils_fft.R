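#' @include core_model.R
NULL

## DFT sample frequencies in cycles/sample, fftshift-free ordering
.fftFreq <- function(n) {
  k <- 0:(n - 1L)
  ifelse(k > n %/% 2, k - n, k) / n
}

.fft2 <- function(x) stats::fft(x)
.ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

## |f|^2 grid in cycles per unit length, for an h x w image with pixel p
.freqSq <- function(h, w, p) {
  fy <- .fftFreq(h) / p
  fx <- .fftFreq(w) / p
  outer(fy^2, fx^2, `+`)
}

## symmetric (mirror) padding by `pad` pixels on every side
.padSym <- function(img, pad) {
  if (pad == 0L) return(img)
  h <- nrow(img); w <- ncol(img)
  py <- min(pad, h); px <- min(pad, w)
  ridx <- c(rev(seq_len(py)), seq_len(h), h + 1L - seq_len(py))
  cidx <- c(rev(seq_len(px)), seq_len(w), w + 1L - seq_len(px))
  img[ridx, cidx, drop = FALSE]
}

.cropSym <- function(img, pad, h, w) {
  if (pad == 0L) return(img)
  py <- min(pad, h); px <- min(pad, w)
  img[py + seq_len(h), px + seq_len(w), drop = FALSE]
}

## centered moving average with replicated edges (odd width)
.movAvg <- function(x, width) {
  stopifnot(width %% 2L == 1L, width >= 1L)
  if (width == 1L) return(x)
  half <- (width - 1L) %/% 2L
  xp <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / width, width), sides = 2L))[half + seq_along(x)]
}

.rmse <- function(a, b) sqrt(mean((a - b)^2))

.relL2 <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))

.nextPow2 <- function(n) 2L^ceiling(log2(n))

.deg2rad <- function(x) x * pi / 180
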