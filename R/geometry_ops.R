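#' @include flat_fielding.R
NULL

#' Estimate the rotation-axis column from a 0/180-degree pair
#'
#' The 180-degree projection is mirrored horizontally; the shift
#' maximizing the normalized cross-correlation against the 0-degree
#' projection (integer peak plus parabolic subpixel refinement) gives the
#' axis as \code{(W - 1)/2 + s/2}. For half-acquisition scans, where only
#' the overlap region has a mirror counterpart, the correlation is
#' normalized per shift over the overlapping columns only.
#'
#' @param proj0deg,proj180deg flat-corrected projections (h x w) at
#'   nominally 0 and 180 degrees.
#' @param maxShift largest |shift| searched, pixels (default: W - 2).
#' @return axis column (fractional 0-based pixels), with attributes
#'   \code{"shift"}, \code{"peak"} (peak correlation) and, when the peak
#'   correlation is below 0.2, \code{"lowConfidence" = TRUE} plus a
#'   warning.
#' @export
estimateAxisPosition <- function(proj0deg, proj180deg, maxShift = NULL) {
  if (!identical(dim(proj0deg), dim(proj180deg)))
    stop("the two projections must have the same height and width")
  W <- ncol(proj0deg)
  if (is.null(maxShift)) maxShift <- W - 2L
  ## light 3-tap smoothing along the detector: propagation fringes are
  ## near-pixel-period and decorrelate integer-lag matching otherwise
  smooth3 <- function(m) {
    n <- ncol(m)
    (m[, c(1L, 1:(n - 1L)), drop = FALSE] + 2 * m +
       m[, c(2:n, n), drop = FALSE]) / 4
  }
  p0 <- smooth3(proj0deg)
  mir <- smooth3(proj180deg)[, W:1, drop = FALSE]
  sdAll <- sd(p0)
  shifts <- -maxShift:maxShift
  ncc <- vapply(shifts, function(s) {
    ## compare p0[, j] with mir[, j - s] over the overlapping columns;
    ## the ends of the overlap coincide with the detector edges of the
    ## two views, where truncation diffraction makes them disagree, so
    ## trim a margin at both ends
    j <- seq_len(W)
    jm <- j - s
    ok <- jm >= 1L & jm <= W
    if (sum(ok) < max(8L, W %/% 8L)) return(-Inf)
    idx <- which(ok)
    margin <- min(8L, length(idx) %/% 4L)
    if (margin > 0L)
      ok[c(head(idx, margin), tail(idx, margin))] <- FALSE
    a <- as.vector(p0[, j[ok], drop = FALSE])
    b <- as.vector(mir[, jm[ok], drop = FALSE])
    sa <- sd(a); sb <- sd(b)
    if (sa == 0 || sb == 0) return(0)
    ## a nearly featureless overlap (air only) carries no registration
    ## information however well it correlates
    if (sdAll > 0 && (sa < 0.05 * sdAll || sb < 0.05 * sdAll)) return(-Inf)
    mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
  }, numeric(1))
  i <- which.max(ncc)
  peak <- ncc[i]
  s <- shifts[i]
  ## parabolic subpixel refinement on the three points around the peak
  if (i > 1L && i < length(shifts) && is.finite(ncc[i - 1L]) &&
      is.finite(ncc[i + 1L])) {
    d1 <- (ncc[i + 1L] - ncc[i - 1L]) / 2
    d2 <- ncc[i + 1L] - 2 * ncc[i] + ncc[i - 1L]
    if (d2 < 0) s <- s - d1 / d2
  }
  axis <- (W - 1) / 2 + s / 2
  attr(axis, "shift") <- s
  attr(axis, "peak") <- peak
  if (!is.finite(peak) || peak < 0.2) {
    warning("low-confidence axis estimate: correlation peak ",
            sprintf("%.3f", max(peak, 0)), " below 0.2")
    attr(axis, "lowConfidence") <- TRUE
  }
  axis
}

## stitch one theta / theta+180 row pair onto the extended grid.
## u-coordinate: signed detector offset from the rotation axis, pixels.
.stitchRowPair <- function(rowTheta, rowOpp, axis, W, Wp, R,
                           blend = "ramp") {
  uk <- (0:(Wp - 1)) - R
  uOrig <- (0:(W - 1)) - axis          # increasing
  uMirr <- axis - ((W - 1):0)          # increasing (reversed row)
  vO <- approx(uOrig, rowTheta, xout = uk, rule = 2)$y
  vM <- approx(uMirr, rev(rowOpp), xout = uk, rule = 2)$y
  loO <- min(uOrig); hiO <- max(uOrig)
  loM <- min(uMirr); hiM <- max(uMirr)
  inO <- uk >= loO - 0.5 & uk <= hiO + 0.5
  inM <- uk >= loM - 0.5 & uk <= hiM + 0.5
  out <- numeric(Wp)
  out[inO & !inM] <- vO[inO & !inM]
  out[inM & !inO] <- vM[inM & !inO]
  ov <- inO & inM
  if (any(ov)) {
    lo <- max(loO, loM); hi <- min(hiO, hiM)
    wO <- switch(blend,
      ramp = if (hiO >= hiM) (uk[ov] - lo) / max(hi - lo, 1) else
                             (hi - uk[ov]) / max(hi - lo, 1),
      cut = as.numeric(if (hiO >= hiM) uk[ov] >= (lo + hi) / 2 else
                                       uk[ov] <= (lo + hi) / 2),
      cosine = {
        t <- (uk[ov] - lo) / max(hi - lo, 1)
        if (hiO >= hiM) (1 - cos(pi * t)) / 2 else (1 + cos(pi * t)) / 2
      })
    wO <- pmin(pmax(wO, 0), 1)
    out[ov] <- wO * vO[ov] + (1 - wO) * vM[ov]
  }
  out
}

#' Stitch a 360-degree offset-axis sinogram into a 180-degree one
#'
#' Rows at angle theta are paired with the horizontally mirrored rows at
#' theta + 180 degrees; the two half-views are placed on a common
#' extended detector grid centered on the rotation axis, and the overlap
#' region (width about \code{2 W - W'}) is blended. The output width is
#' \code{W' = round(2 * axis + 1)} when the axis lies in the right half
#' of the detector (symmetric formula for the left half), and the output
#' keeps the first half of the input angles.
#'
#' @param sino360 a [Sinogram-class] over a full turn with an even number
#'   of rows.
#' @param axisPosition rotation-axis column; defaults to the sinogram's.
#' @param blend overlap blend: \code{"ramp"} (linear, default),
#'   \code{"cut"} (hard), or \code{"cosine"}.
#' @return a [Sinogram-class] over 180 degrees with nearly doubled width;
#'   its \code{axisPosition} is the center of the new grid.
#' @export
stitchHalfAcquisition <- function(sino360, axisPosition = NULL,
                                  blend = c("ramp", "cut", "cosine")) {
  stopifnot(is(sino360, "Sinogram"))
  blend <- match.arg(blend)
  v <- sino360@values
  n <- nrow(v)
  if (n %% 2L != 0L) stop("an even number of angle rows is required")
  span <- max(sino360@angles) - min(sino360@angles)
  if (span < 360 - .angleSpanTol(sino360@angles))
    stop("sinogram does not cover a full turn (span ", round(span, 2), " deg)")
  W <- ncol(v)
  axis <- if (is.null(axisPosition)) sino360@axisPosition else axisPosition
  if (axis < 0 || axis > W - 1)
    stop("axis must lie inside the detector")
  R <- max(axis, W - 1 - axis)
  Wp <- as.integer(round(2 * R + 1))
  overlap <- 2L * W - Wp
  if (overlap >= W)
    stop("degenerate overlap: axis is at the detector center; ",
         "use scan mode 'half_turn_180' instead")
  half <- n %/% 2L
  out <- matrix(0, half, Wp)
  for (i in seq_len(half))
    out[i, ] <- .stitchRowPair(v[i, ], v[i + half, ], axis, W, Wp, R, blend)
  sinogram(out, sino360@angles[seq_len(half)], axisPosition = R,
           pixelSize = sino360@pixelSize, rowIndex = sino360@rowIndex)
}

#' Extract one detector row as a sinogram
#'
#' @param ps a [ProjectionSet-class] (typically raw counts) or a plain
#'   n_proj x h x w array of flat-corrected projections (then supply
#'   \code{geometry}).
#' @param rowIndex 0-based detector row.
#' @param geometry required when \code{ps} is a plain array.
#' @return a [Sinogram-class]: that row across all projections, in angle
#'   order, values preserved bit-exactly.
#' @export
extractSinogram <- function(ps, rowIndex, geometry = NULL) {
  if (is(ps, "ProjectionSet")) {
    stack <- ps@projections
    geometry <- ps@geometry
  } else {
    stack <- ps
    if (is.null(geometry)) stop("'geometry' is required for a plain array")
  }
  h <- dim(stack)[2L]
  if (rowIndex < 0L || rowIndex > h - 1L)
    stop("row index ", rowIndex, " outside [0, ", h - 1L, "]")
  sinogram(stack[, rowIndex + 1L, ], geometry@angles,
           axisPosition = geometry@axisPosition,
           pixelSize = geometry@pixelSize, rowIndex = as.integer(rowIndex))
}
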