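#' @include phase_retrieval.R
NULL

.checkSinoFinite <- function(v) {
  if (any(!is.finite(v))) stop("sinogram contains non-finite values")
}

.checkSpan180 <- function(angs) {
  span <- max(angs) - min(angs)
  if (span < 180 - .angleSpanTol(angs))
    stop("angle span ", round(span, 2),
         " deg is below the 180 deg required for reconstruction")
}

#' Discrete Radon forward projection
#'
#' Line-integral forward projection of a square slice with the same
#' pixel-driven linear-interpolation projector used by [sirt()] (and
#' adjoint to the [fbp()] back projector), scaled by the pixel size so
#' the output carries physical line-integral units.
#'
#' @param slice a [ReconSlice-class] or square matrix.
#' @param anglesDeg projection angles, degrees.
#' @param axisPosition rotation-axis column on the detector; default:
#'   detector center.
#' @param detectorWidth detector width; default: slice width.
#' @param pixelSize pixel size, m (required when `slice` is a matrix).
#' @param supersample sub-pixel sampling factor per axis (default 2).
#' @return a [Sinogram-class].
#' @export
radonForward <- function(slice, anglesDeg, axisPosition = NULL,
                         detectorWidth = NULL, pixelSize = NULL,
                         supersample = 2L) {
  if (is(slice, "ReconSlice")) {
    img <- slice@values
    if (is.null(pixelSize)) pixelSize <- slice@pixelSize
  } else {
    img <- slice
    if (is.null(pixelSize)) stop("'pixelSize' is required for a plain matrix")
  }
  if (nrow(img) != ncol(img)) stop("slice must be square")
  if (is.null(detectorWidth)) detectorWidth <- ncol(img)
  if (is.null(axisPosition)) axisPosition <- (detectorWidth - 1) / 2
  v <- cpp_forward(img, .deg2rad(anglesDeg), axisPosition,
                   as.integer(detectorWidth), as.integer(supersample)) *
    pixelSize
  sinogram(v, anglesDeg, axisPosition, pixelSize)
}

## ramp filter times apodization window, length nfft, cycles/sample.
## The ramp is the DFT of the discrete Ram-Lak kernel (1/4 at 0,
## -1/(pi n)^2 at odd lags) rather than naively sampled |f|, which would
## bias the reconstruction low by a few percent at low frequencies.
.fbpFilter <- function(nfft, filterName) {
  f <- abs(.fftFreq(nfft))
  kern <- numeric(nfft)
  kern[1L] <- 0.25
  odd <- seq(1L, nfft %/% 2L, by = 2L)
  kern[1L + odd] <- -1 / (pi * odd)^2
  kern[nfft + 1L - odd] <- -1 / (pi * odd)^2
  ramp <- 2 * Re(stats::fft(kern))
  w <- switch(filterName,
    ramlak = rep(1, nfft),
    shepp_logan = ifelse(f > 0, sin(pi * f) / (pi * f), 1),
    hann = 0.5 * (1 + cos(2 * pi * f)),
    stop("unknown FBP filter '", filterName, "'"))
  ramp * w
}

#' Filtered back projection
#'
#' Each sinogram row is zero-padded to at least twice its width (next
#' power of two), filtered in the Fourier domain by |f| times the chosen
#' apodization window, and back-projected with linear interpolation
#' about the rotation axis. The result is scaled by
#' \code{pi / (2 n_angles) / pixelSize} so a sinogram of line integrals
#' of a quantity q reconstructs q in its own units per length.
#'
#' @param sino a [Sinogram-class] spanning at least 180 degrees, finite
#'   values only.
#' @param filterName \code{"ramlak"}, \code{"shepp_logan"} or
#'   \code{"hann"}.
#' @param axisPosition override of the sinogram's axis column.
#' @param outputSize slice side, pixels; default: detector width.
#' @param quantity physical quantity tag of the output slice.
#' @param supersample projector supersampling (matched to [radonForward()]).
#' @return a [ReconSlice-class].
#' @export
fbp <- function(sino, filterName = c("ramlak", "shepp_logan", "hann"),
                axisPosition = NULL, outputSize = NULL,
                quantity = "attenuation_coefficient", supersample = 2L) {
  stopifnot(is(sino, "Sinogram"))
  filterName <- match.arg(filterName)
  v <- sino@values
  .checkSinoFinite(v)
  .checkSpan180(sino@angles)
  axis <- if (is.null(axisPosition)) sino@axisPosition else axisPosition
  W <- ncol(v)
  n <- if (is.null(outputSize)) W else as.integer(outputSize)
  nfft <- .nextPow2(2L * W)
  fl <- .fbpFilter(nfft, filterName)
  pad <- matrix(0, nfft, nrow(v))
  pad[seq_len(W), ] <- t(v)
  filtered <- Re(mvfft(mvfft(pad) * fl, inverse = TRUE)) / nfft
  q <- t(filtered[seq_len(W), , drop = FALSE])
  back <- cpp_backproject(q, .deg2rad(sino@angles), axis, n,
                          as.integer(supersample))
  scale <- pi / (2 * length(sino@angles)) / sino@pixelSize
  reconSlice(back * scale, sino@pixelSize, quantity)
}

#' Simultaneous iterative reconstruction technique (SIRT)
#'
#' Classic SIRT with inverse row/column-sum weighting:
#' \code{x <- x + C A' R (b - A x)} per iteration, where \code{A} is the
#' same linear-interpolation forward projector as [radonForward()] and
#' \code{A'} its exact adjoint, \code{R} and \code{C} the reciprocal
#' row/column sums. An optional non-negativity clamp is applied each
#' iteration. The data residual is recorded per iteration; three
#' consecutive residual increases abort with diagnostics.
#'
#' @param sino a [Sinogram-class].
#' @param nIterations number of iterations, >= 1.
#' @param nonneg clamp negative pixels to zero each iteration.
#' @param axisPosition override of the sinogram's axis column.
#' @param outputSize slice side, pixels; default: detector width.
#' @param quantity physical quantity tag of the output slice.
#' @param supersample projector supersampling.
#' @return a [ReconSlice-class] with attribute \code{"residuals"}: the
#'   L2 data residual after each iteration.
#' @export
sirt <- function(sino, nIterations = 100L, nonneg = TRUE,
                 axisPosition = NULL, outputSize = NULL,
                 quantity = "attenuation_coefficient", supersample = 2L) {
  stopifnot(is(sino, "Sinogram"))
  if (nIterations < 1L) stop("'nIterations' must be >= 1")
  b <- sino@values
  .checkSinoFinite(b)
  axis <- if (is.null(axisPosition)) sino@axisPosition else axisPosition
  W <- ncol(b)
  n <- if (is.null(outputSize)) W else as.integer(outputSize)
  p <- sino@pixelSize
  rad <- .deg2rad(sino@angles)
  ss <- as.integer(supersample)
  A <- function(x) cpp_forward(x, rad, axis, W, ss) * p
  At <- function(y) cpp_backproject(y, rad, axis, n, ss) * p
  rowsum_ <- A(matrix(1, n, n))
  colsum_ <- At(matrix(1, nrow(b), W))
  Rw <- ifelse(rowsum_ > 0, 1 / rowsum_, 0)
  Cw <- ifelse(colsum_ > 0, 1 / colsum_, 0)
  x <- matrix(0, n, n)
  residuals <- numeric(nIterations)
  up <- 0L
  for (it in seq_len(nIterations)) {
    r <- b - A(x)
    residuals[it] <- sqrt(sum(r^2))
    if (it > 1L && residuals[it] > residuals[it - 1L] * 1.001) {
      up <- up + 1L
      if (up >= 3L)
        stop("SIRT diverging: residual grew over 3 consecutive iterations (",
             paste(signif(residuals[(it - 3L):it], 6), collapse = " -> "), ")")
    } else up <- 0L
    x <- x + Cw * At(Rw * r)
    if (nonneg) x[x < 0] <- 0
  }
  out <- reconSlice(x, p, quantity)
  attr(out@values, "residuals") <- NULL
  attr(out, "residuals") <- residuals
  out
}
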