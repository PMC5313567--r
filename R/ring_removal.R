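#' @include geometry_ops.R
NULL

#' Fourier-domain sinogram de-striping (Raven-type filter)
#'
#' Ring artifacts originate from detector-gain errors that are constant
#' in angle, i.e. concentrated on the lowest angular-frequency lines of
#' the sinogram's 2-D spectrum while being sharp in the detector
#' coordinate. The filter takes the 2-D DFT of the sinogram and, on the
#' \code{nAngularLines} lowest angular-frequency lines (|m| <
#' nAngularLines), multiplies the detector-frequency spectrum by a
#' Butterworth low-pass \code{H(u) = 1 / (1 + (u/u0)^(2 order))}; all
#' other lines pass unchanged. H(0) = 1, so the sinogram mean is
#' preserved. The classical filter uses only the zero angular-frequency
#' line; the line count, cutoff and order are the tunable modification.
#'
#' @param sino a [Sinogram-class] (flat-corrected, possibly
#'   phase-retrieved; never raw counts).
#' @param u0 Butterworth cutoff, cycles/pixel, in (0, 0.5).
#' @param order Butterworth order, >= 1.
#' @param nAngularLines number of low angular-frequency lines to filter
#'   (counting |m| < nAngularLines), >= 1.
#' @return de-striped [Sinogram-class].
#' @export
ravenFilter <- function(sino, u0 = 0.05, order = 4L, nAngularLines = 2L) {
  stopifnot(is(sino, "Sinogram"))
  if (u0 <= 0 || u0 >= 0.5) stop("'u0' must be in (0, 0.5) cycles/pixel")
  if (order < 1L) stop("'order' must be >= 1")
  if (nAngularLines < 1L) stop("'nAngularLines' must be >= 1")
  v <- sino@values
  n <- nrow(v); W <- ncol(v)
  F <- .fft2(v)
  m <- .fftFreq(n) * n                        # integer angular frequencies
  u <- abs(.fftFreq(W))                       # detector freq, cycles/pixel
  H <- 1 / (1 + (u / u0)^(2 * order))
  rows <- which(abs(m) < nAngularLines)
  F[rows, ] <- sweep(F[rows, , drop = FALSE], 2L, H, `*`)
  out <- .ifft2(F)
  resid <- max(abs(Im(out))) / max(diff(range(v)), .Machine$double.eps)
  if (resid > 1e-8)
    warning("unexpected imaginary residue after filtering: ", signif(resid, 3))
  s2 <- sino
  s2@values <- Re(out)
  s2
}

#' Column-normalization sinogram de-striping
#'
#' Simple representative of the statistical de-striping family: the
#' per-column angular mean \code{c(x)} is computed, smoothed into the
#' trend \code{chat(x)} (a running median of width 3 against isolated
#' stripe columns, then a moving average of the given width), and each
#' column is divided by \code{c(x) / chat(x)}. Stripes (column-wise gain
#' errors) are flattened while slowly varying structure passes through;
#' the median prefilter keeps a stripe's own column mean out of its
#' trend estimate, so isolated stripes are restored essentially exactly.
#'
#' @param sino a [Sinogram-class] with strictly positive column means
#'   (i.e. run after flat fielding).
#' @param smoothingWidth moving-average width, odd, >= 3.
#' @return de-striped [Sinogram-class].
#' @export
columnNormalizationFilter <- function(sino, smoothingWidth = 9L) {
  stopifnot(is(sino, "Sinogram"))
  if (smoothingWidth < 3L || smoothingWidth %% 2L == 0L)
    stop("'smoothingWidth' must be odd and >= 3")
  v <- sino@values
  cx <- colMeans(v)
  if (any(cx <= 0))
    stop("non-positive column means; the filter must run after flat fielding")
  chat <- .movAvg(stats::runmed(cx, 3L, endrule = "constant"), smoothingWidth)
  s2 <- sino
  s2@values <- sweep(v, 2L, chat / cx, `*`)
  s2
}

#' Residual stripe energy of a sinogram
#'
#' Variance over detector columns of the angular mean after removing the
#' smooth trend — the quantity a de-striping filter is meant to reduce.
#'
#' @param sino a [Sinogram-class].
#' @param trendWidth moving-average width used for the smooth trend.
#' @return scalar stripe energy.
#' @export
stripeEnergy <- function(sino, trendWidth = 15L) {
  stopifnot(is(sino, "Sinogram"))
  cx <- colMeans(sino@values)
  var(cx - .movAvg(cx, trendWidth))
}

#' Ring-artifact energy of a reconstructed slice
#'
#' Rings are deviations that are constant along circles about the
#' rotation center. The statistic is the mean over radii of the variance
#' of the slice on each circle, minus the same statistic on a reference
#' (ground truth or a smoothed copy) so that genuine angular structure of
#' the object is discounted. Radially symmetric images score ~0.
#'
#' @param slice a [ReconSlice-class].
#' @param reference a matching [ReconSlice-class] or matrix carrying the
#'   ring-free reference; default: the slice smoothed by a 5x5 box
#'   filter (a partial reference; prefer ground truth when available).
#' @param center slice center (x, y), 0-based pixels; default: geometric
#'   center.
#' @param maxRadius largest radius used, pixels; default: inscribed circle.
#' @return scalar ring energy (can be ~0 or slightly negative for
#'   ring-free slices).
#' @export
ringEnergy <- function(slice, reference = NULL, center = NULL,
                       maxRadius = NULL) {
  stopifnot(is(slice, "ReconSlice"))
  v <- slice@values
  n <- nrow(v)
  if (is.null(center)) center <- c((n - 1) / 2, (n - 1) / 2)
  if (is.null(maxRadius)) maxRadius <- floor((n - 1) / 2)
  ref <- if (is.null(reference)) .boxFilter(v, 5L)
         else if (is(reference, "ReconSlice")) reference@values
         else reference
  X <- matrix(0:(n - 1), n, n, byrow = TRUE)
  Y <- matrix(0:(n - 1), n, n)
  r <- round(sqrt((X - center[1L])^2 + (Y - center[2L])^2))
  ok <- r >= 1 & r <= maxRadius
  stat <- function(img) {
    mean(tapply(img[ok], r[ok], var), na.rm = TRUE)
  }
  stat(v) - stat(ref)
}

## 2-D box filter with replicated edges
.boxFilter <- function(img, width) {
  half <- (width - 1L) %/% 2L
  n <- nrow(img); m <- ncol(img)
  ridx <- c(rep(1L, half), seq_len(n), rep(n, half))
  cidx <- c(rep(1L, half), seq_len(m), rep(m, half))
  pad <- img[ridx, cidx]
  out <- matrix(0, n, m)
  for (dy in 0:(width - 1L))
    for (dx in 0:(width - 1L))
      out <- out + pad[dy + seq_len(n), dx + seq_len(m)]
  out / width^2
}
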