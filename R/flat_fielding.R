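#' @include simulator.R
NULL

#' Conventional flat-field normalization
#'
#' \code{N = (P - meanDark) / (meanFlat - meanDark)}. The denominator is
#' clamped below at \code{epsFactor * max(meanFlat - meanDark)} and the
#' result clipped to \code{[0, clipMax]} so that a downstream logarithm
#' never sees non-positive values.
#'
#' @param projection raw projection (h x w), counts.
#' @param meanFlat,meanDark mean flat / dark frames, counts.
#' @param epsFactor relative clamp on the denominator (default 1e-6).
#' @param clipMax upper clip of the normalized image (default 10).
#' @return normalized projection in [0, clipMax].
#' @export
conventionalFlatField <- function(projection, meanFlat, meanDark,
                                  epsFactor = 1e-6, clipMax = 10) {
  if (!identical(dim(projection), dim(meanFlat)) ||
      !identical(dim(projection), dim(meanDark)))
    stop("projection, flat and dark shapes must match")
  den <- meanFlat - meanDark
  if (mean(den <= 0) > 0.01)
    stop("bad flats: mean flat does not exceed mean dark over >1% of pixels")
  den <- pmax(den, epsFactor * max(den))
  out <- (projection - meanDark) / den
  pmin(pmax(out, 0), clipMax)
}

#' Principal-component (eigen) flat fields
#'
#' Dark-subtracted flats are mean-centered and decomposed by singular
#' value decomposition; the leading right-singular images form an
#' orthonormal basis of the flat-field variability (beam drift, moving
#' structure). The decomposition works from hundreds of flats down to as
#' few as two; identical flats yield an empty basis.
#'
#' @param flatStack n x h x w array of flat frames (n >= 2).
#' @param darkStack m x h x w array of dark frames.
#' @param nComponents number of components to keep; must be < n. Components
#'   whose singular values are at numerical noise level are dropped.
#' @return an [EigenFlatBasis-class].
#' @export
computeEigenFlats <- function(flatStack, darkStack, nComponents = 3L) {
  stopifnot(length(dim(flatStack)) == 3L, length(dim(darkStack)) == 3L)
  n <- dim(flatStack)[1L]
  if (n < 2L) stop("at least two flat frames are required")
  if (nComponents >= n)
    stop("'nComponents' must be smaller than the number of flats")
  h <- dim(flatStack)[2L]; w <- dim(flatStack)[3L]
  meanDark <- apply(darkStack, c(2, 3), mean)
  meanFlat <- apply(flatStack, c(2, 3), mean)
  X <- matrix(aperm(flatStack, c(2, 3, 1)), ncol = n)   # npix x n
  X <- X - as.vector(meanFlat)                          # dark level cancels
  sv <- svd(X, nu = min(n, nComponents), nv = 0)
  tot <- sum(sv$d^2)
  keep <- if (tot > 0) which(sv$d[seq_len(min(n, nComponents))] >
                               max(sv$d) * 1e-7 & sv$d[seq_len(min(n, nComponents))]^2 >
                               tot * 1e-12)
          else integer(0)
  k <- length(keep)
  comps <- array(0, c(k, h, w))
  for (j in seq_len(k)) comps[j, , ] <- matrix(sv$u[, keep[j]], h, w)
  new("EigenFlatBasis",
      meanFlat = meanFlat, meanDark = meanDark, components = comps,
      explainedVariance = if (k) sv$d[keep]^2 / tot else numeric(0))
}

#' Dynamic (eigen-flat-field) normalization
#'
#' Fits a linear combination of the eigen flat fields to each projection
#' individually: the residual \code{P - meanDark - (meanFlat - meanDark)}
#' is regressed onto the eigen images over the estimation region (default:
#' the whole frame; typically user-specified air columns), and the fitted
#' combination is added to the denominator before normalizing. With an
#' empty basis this reduces exactly to [conventionalFlatField()].
#'
#' @param projection raw projection (h x w), counts.
#' @param basis an [EigenFlatBasis-class].
#' @param estimationRegion optional logical mask (h x w) or column index
#'   vector (1-based) restricting the weight fit, e.g. air-only columns.
#' @param epsFactor,clipMax clamping as in [conventionalFlatField()].
#' @return normalized projection; attribute \code{"weights"} carries the
#'   fitted eigen-flat weights.
#' @export
dynamicFlatField <- function(projection, basis, estimationRegion = NULL,
                             epsFactor = 1e-6, clipMax = 10) {
  stopifnot(is(basis, "EigenFlatBasis"))
  k <- if (length(basis@components)) dim(basis@components)[1L] else 0L
  if (k == 0L)
    return(conventionalFlatField(projection, basis@meanFlat, basis@meanDark,
                                 epsFactor, clipMax))
  if (!identical(dim(projection), dim(basis@meanFlat)))
    stop("projection and basis frame shapes must match")
  mask <- rep(TRUE, length(projection))
  if (!is.null(estimationRegion)) {
    if (is.logical(estimationRegion)) {
      mask <- as.vector(estimationRegion)
    } else {
      m <- matrix(FALSE, nrow(projection), ncol(projection))
      m[, estimationRegion] <- TRUE
      mask <- as.vector(m)
    }
  }
  resid <- as.vector(projection - basis@meanFlat)
  A <- matrix(aperm(basis@components, c(2, 3, 1)), ncol = k)
  fit <- tryCatch(qr.coef(qr(A[mask, , drop = FALSE]), resid[mask]),
                  error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(fit))) {
    warning("singular eigen-flat normal equations; ",
            "falling back to conventional flat fielding")
    return(conventionalFlatField(projection, basis@meanFlat, basis@meanDark,
                                 epsFactor, clipMax))
  }
  den <- (basis@meanFlat - basis@meanDark) +
    matrix(A %*% fit, nrow(projection), ncol(projection))
  den <- pmax(den, epsFactor * max(basis@meanFlat - basis@meanDark))
  out <- pmin(pmax((projection - basis@meanDark) / den, 0), clipMax)
  attr(out, "weights") <- as.numeric(fit)
  out
}

#' Flat-field a whole projection stack
#'
#' Applies [conventionalFlatField()] or [dynamicFlatField()] frame by
#' frame, pooling the before/after flats for the mean flat and the PCA.
#'
#' @param ps a [ProjectionSet-class].
#' @param method \code{"conventional"} or \code{"dynamic"}.
#' @param nComponents eigen components for the dynamic method.
#' @param estimationRegion see [dynamicFlatField()].
#' @param epsFactor,clipMax clamping constants.
#' @return n_proj x h x w array of normalized projections; for the
#'   dynamic method the eigen basis is attached as attribute
#'   \code{"basis"}.
#' @export
flatFieldStack <- function(ps, method = c("conventional", "dynamic"),
                           nComponents = 3L, estimationRegion = NULL,
                           epsFactor = 1e-6, clipMax = 10) {
  stopifnot(is(ps, "ProjectionSet"))
  method <- match.arg(method)
  allFlats <- flats(ps, "all")
  meanDark <- apply(ps@darks, c(2, 3), mean)
  meanFlat <- apply(allFlats, c(2, 3), mean)
  np <- nProjections(ps)
  out <- array(0, dim(ps@projections))
  h <- dim(ps@projections)[2L]; w <- dim(ps@projections)[3L]
  if (method == "conventional") {
    for (i in seq_len(np))
      out[i, , ] <- conventionalFlatField(
        matrix(ps@projections[i, , ], h, w), meanFlat, meanDark,
        epsFactor, clipMax)
  } else {
    nf <- dim(allFlats)[1L]
    if (nf < 2L)
      stop("dynamic flat fielding requires at least two flat frames")
    basis <- computeEigenFlats(allFlats, ps@darks,
                               nComponents = min(nComponents, nf - 1L))
    for (i in seq_len(np))
      out[i, , ] <- dynamicFlatField(matrix(ps@projections[i, , ], h, w),
                                     basis, estimationRegion, epsFactor,
                                     clipMax)
    attr(out, "basis") <- basis
  }
  out
}
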