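#' @include AllGenerics.R
NULL

## Planck constant times speed of light, CODATA 2018, expressed in keV * m
## so that lambda[m] = .hc / E[keV].
.hc_keV_m <- 1.239841984e-9

.scan_modes <- c("half_turn_180", "full_turn_360_offset")
.quantities <- c("attenuation_coefficient", "delta", "phase")

## ---------------------------------------------------------------------------
## Geometry
## ---------------------------------------------------------------------------

#' Acquisition geometry for a parallel-beam PBI scan
#'
#' Carries the monochromatic beam energy (and the wavelength derived from
#' it), detector pixel size, sample-to-detector propagation distance, the
#' ordered rotation-angle list, the rotation-axis position on the detector
#' and the scan mode. Conventions: columns are indexed 0-based at pixel
#' centers and \code{axisPosition} is a fractional column index; angles are
#' stored in degrees (beamline logs use degrees) and converted to radians
#' internally where needed.
#'
#' @slot energy photon energy, keV.
#' @slot wavelength wavelength, m; always \code{hc / energy}.
#' @slot pixelSize detector pixel size, m.
#' @slot distance sample-to-detector propagation distance, m.
#' @slot angles ordered rotation angles, degrees, strictly increasing.
#' @slot axisPosition rotation-axis column, fractional 0-based pixels.
#' @slot detectorWidth detector width, pixels.
#' @slot scanMode \code{"half_turn_180"} or \code{"full_turn_360_offset"}.
#'
#' @seealso [geometry()] constructor, [energyToWavelength()]
#' @export
setClass("Geometry",
  representation(
    energy = "numeric",
    wavelength = "numeric",
    pixelSize = "numeric",
    distance = "numeric",
    angles = "numeric",
    axisPosition = "numeric",
    detectorWidth = "integer",
    scanMode = "character"
  )
)

.angleSpanTol <- function(angles) {
  ## generous allowance for the customary missing end point of the angular
  ## grid: two median steps, at least half a degree
  if (length(angles) < 2L) return(Inf)
  max(2 * median(diff(angles)), 0.5)
}

setValidity("Geometry", function(object) {
  msg <- character()
  if (length(object@energy) != 1L || !is.finite(object@energy) || object@energy <= 0)
    msg <- c(msg, "'energy' must be a single positive number (keV)")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "'pixelSize' must be a single positive number (m)")
  if (length(object@distance) != 1L || object@distance < 0)
    msg <- c(msg, "'distance' must be a single non-negative number (m)")
  if (length(object@angles) < 1L)
    msg <- c(msg, "'angles' must be non-empty")
  if (length(object@angles) > 1L && any(diff(object@angles) <= 0))
    msg <- c(msg, "'angles' must be strictly increasing")
  if (length(object@energy) == 1L && object@energy > 0) {
    lam <- .hc_keV_m / object@energy
    if (abs(object@wavelength - lam) > 1e-9 * lam)
      msg <- c(msg, "'wavelength' inconsistent with hc/energy")
  }
  if (!(object@scanMode %in% .scan_modes))
    msg <- c(msg, sprintf("'scanMode' must be one of: %s",
                          paste(.scan_modes, collapse = ", ")))
  if (length(object@detectorWidth) == 1L && object@detectorWidth >= 1L &&
      length(object@axisPosition) == 1L &&
      (object@axisPosition < 0 || object@axisPosition > object@detectorWidth - 1L))
    msg <- c(msg, "'axisPosition' must lie inside the detector")
  if (length(object@angles) >= 2L && object@scanMode %in% .scan_modes) {
    span <- max(object@angles) - min(object@angles)
    need <- if (object@scanMode == "half_turn_180") 180 else 360
    if (span < need - .angleSpanTol(object@angles))
      msg <- c(msg, sprintf(
        "angle list spans %.2f deg, below the %g deg required by scan mode '%s'",
        span, need, object@scanMode))
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## RefractiveMap
## ---------------------------------------------------------------------------

#' Paired delta / beta maps of a phantom slice
#'
#' The X-ray refractive index is written n = 1 - delta + i beta; delta
#' (decrement from unity) governs phase shift, beta absorption. Both maps
#' share one square grid with a physical pixel size.
#'
#' @slot delta 2-D map of delta, dimensionless.
#' @slot beta 2-D map of beta, dimensionless, non-negative.
#' @slot pixelSize grid pixel size, m.
#' @export
setClass("RefractiveMap",
  representation(delta = "matrix", beta = "matrix", pixelSize = "numeric"))

setValidity("RefractiveMap", function(object) {
  msg <- character()
  if (!identical(dim(object@delta), dim(object@beta)))
    msg <- c(msg, "'delta' and 'beta' must have identical shape")
  if (any(object@beta < 0))
    msg <- c(msg, "'beta' must be non-negative everywhere")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "'pixelSize' must be a single positive number (m)")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## ProjectionSet
## ---------------------------------------------------------------------------

#' Raw projection stack plus flat and dark frames
#'
#' The standard acquisition payload: detector counts for each rotation
#' angle, flat (white, no-sample) frames collected before and possibly
#' after the scan, and dark (no-beam) frames, together with the geometry.
#' Stacks are 3-D arrays ordered \code{(frame, row, column)}; frame order
#' is acquisition order, equal to angle order.
#'
#' @slot projections n_proj x height x width array, detector counts.
#' @slot flatsBefore flat frames collected before the scan (n x h x w).
#' @slot flatsAfter flat frames collected after the scan; may be empty.
#' @slot darks dark frames (n x h x w).
#' @slot geometry a [Geometry-class].
#' @export
setClass("ProjectionSet",
  representation(
    projections = "array",
    flatsBefore = "array",
    flatsAfter = "array",
    darks = "array",
    geometry = "Geometry"
  )
)

.frameDims <- function(a) if (length(dim(a)) == 3L) dim(a)[2:3] else NULL

setValidity("ProjectionSet", function(object) {
  msg <- character()
  dp <- dim(object@projections)
  if (length(dp) != 3L)
    return("'projections' must be a 3-D array (n_proj x height x width)")
  hw <- dp[2:3]
  for (nm in c("flatsBefore", "flatsAfter", "darks")) {
    a <- slot(object, nm)
    if (length(a) == 0L) next
    if (length(dim(a)) != 3L || !identical(dim(a)[2:3], hw))
      msg <- c(msg, sprintf("'%s' frames must share the projection height x width", nm))
  }
  nfl <- (if (length(object@flatsBefore)) dim(object@flatsBefore)[1L] else 0L) +
         (if (length(object@flatsAfter))  dim(object@flatsAfter)[1L]  else 0L)
  if (nfl < 1L) msg <- c(msg, "at least one flat frame is required")
  if (length(object@darks) == 0L) msg <- c(msg, "at least one dark frame is required")
  if (dp[1L] != length(object@geometry@angles))
    msg <- c(msg, "number of projections must equal length(geometry angles)")
  if (dp[3L] != object@geometry@detectorWidth)
    msg <- c(msg, "projection width must equal geometry detectorWidth")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Sinogram
## ---------------------------------------------------------------------------

#' Single-slice sinogram (angle x detector column)
#'
#' One detector row across all projections, rows ordered by angle.
#'
#' @slot values n_angles x width matrix.
#' @slot angles rotation angles, degrees, one per row.
#' @slot axisPosition rotation-axis column, fractional 0-based pixels.
#' @slot pixelSize detector pixel size, m.
#' @slot rowIndex detector row of origin (0-based), NA if synthetic.
#' @export
setClass("Sinogram",
  representation(
    values = "matrix",
    angles = "numeric",
    axisPosition = "numeric",
    pixelSize = "numeric",
    rowIndex = "integer"
  )
)

setValidity("Sinogram", function(object) {
  msg <- character()
  if (nrow(object@values) != length(object@angles))
    msg <- c(msg, "one angle per sinogram row is required")
  if (length(object@angles) > 1L && any(diff(object@angles) <= 0))
    msg <- c(msg, "sinogram rows must be ordered by strictly increasing angle")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "'pixelSize' must be a single positive number (m)")
  if (length(object@axisPosition) != 1L ||
      object@axisPosition < 0 || object@axisPosition > ncol(object@values) - 1L)
    msg <- c(msg, "'axisPosition' must lie inside the detector")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## ReconSlice
## ---------------------------------------------------------------------------

#' Reconstructed axial slice
#'
#' @slot values square 2-D map.
#' @slot pixelSize slice pixel size, m.
#' @slot quantity physical quantity carried by the map:
#'   \code{"attenuation_coefficient"}, \code{"delta"} or \code{"phase"}.
#' @export
setClass("ReconSlice",
  representation(values = "matrix", pixelSize = "numeric", quantity = "character"))

setValidity("ReconSlice", function(object) {
  msg <- character()
  if (nrow(object@values) != ncol(object@values))
    msg <- c(msg, "'values' must be square")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "'pixelSize' must be a single positive number (m)")
  if (!(object@quantity %in% .quantities))
    msg <- c(msg, sprintf("'quantity' must be one of: %s",
                          paste(.quantities, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## EigenFlatBasis
## ---------------------------------------------------------------------------

#' Eigen-flat-field basis for dynamic flat fielding
#'
#' Principal components of the dark-subtracted, mean-centered flat frames.
#' Components are unit-L2-norm images, mutually orthogonal, ordered by
#' non-increasing explained variance.
#'
#' @slot meanFlat mean flat frame (counts).
#' @slot meanDark mean dark frame (counts).
#' @slot components k x h x w array of eigen flat images; may be empty.
#' @slot explainedVariance fraction of flat-set variance per component.
#' @export
setClass("EigenFlatBasis",
  representation(
    meanFlat = "matrix",
    meanDark = "matrix",
    components = "array",
    explainedVariance = "numeric"
  )
)

setValidity("EigenFlatBasis", function(object) {
  msg <- character()
  k <- if (length(object@components)) dim(object@components)[1L] else 0L
  if (k != length(object@explainedVariance))
    msg <- c(msg, "one explained-variance entry per component is required")
  if (k > 0L && !identical(dim(object@components)[2:3], dim(object@meanFlat)))
    msg <- c(msg, "components must share the mean-flat shape")
  if (k > 1L) {
    V <- matrix(aperm(object@components, c(2, 3, 1)), ncol = k)
    G <- crossprod(V)
    if (max(abs(G - diag(k))) > 1e-6)
      msg <- c(msg, "components must be orthonormal")
    if (any(diff(object@explainedVariance) > 1e-12))
      msg <- c(msg, "'explainedVariance' must be non-increasing")
  }
  if (sum(object@explainedVariance) > 1 + 1e-8)
    msg <- c(msg, "'explainedVariance' must sum to at most 1")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## RetrievalConfig
## ---------------------------------------------------------------------------

#' Configuration for single-distance phase retrieval
#'
#' @slot method \code{"paganin"}, \code{"ctf_pure_phase"} or
#'   \code{"projected_ctf"}.
#' @slot deltaBetaRatio assumed delta/beta of the (homogeneous) sample;
#'   the single tuning parameter of the Paganin TIE-Hom filter.
#' @slot regularization Tikhonov-style constant added to the squared CTF
#'   response; keeps the inversion finite where sin(chi) vanishes.
#' @slot responseClamp chi threshold beyond which the projected-CTF
#'   response is held constant (clamped-sine surrogate).
#' @slot padding symmetric padding (pixels) applied before the DFT.
#' @export
setClass("RetrievalConfig",
  representation(
    method = "character",
    deltaBetaRatio = "numeric",
    regularization = "numeric",
    responseClamp = "numeric",
    padding = "integer"
  )
)

setValidity("RetrievalConfig", function(object) {
  msg <- character()
  if (!(object@method %in% c("paganin", "ctf_pure_phase", "projected_ctf")))
    msg <- c(msg, "unknown retrieval method")
  if (object@deltaBetaRatio <= 0) msg <- c(msg, "'deltaBetaRatio' must be positive")
  if (object@regularization <= 0) msg <- c(msg, "'regularization' must be positive")
  if (object@responseClamp <= 0) msg <- c(msg, "'responseClamp' must be positive")
  if (object@padding < 0L) msg <- c(msg, "'padding' must be non-negative")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "Geometry", function(object) {
  cat(sprintf(
    "Geometry: %.4g keV (lambda %.4g m), pixel %.3g m, distance %.3g m\n",
    object@energy, object@wavelength, object@pixelSize, object@distance))
  cat(sprintf("  %d angles in [%.2f, %.2f] deg, mode %s\n",
              length(object@angles), min(object@angles), max(object@angles),
              object@scanMode))
  cat(sprintf("  detector %d px, axis at column %.3f\n",
              object@detectorWidth, object@axisPosition))
})

setMethod("show", "ProjectionSet", function(object) {
  d <- dim(object@projections)
  nb <- if (length(object@flatsBefore)) dim(object@flatsBefore)[1L] else 0L
  na <- if (length(object@flatsAfter)) dim(object@flatsAfter)[1L] else 0L
  nd <- if (length(object@darks)) dim(object@darks)[1L] else 0L
  cat(sprintf("ProjectionSet: %d projections of %d x %d px\n", d[1L], d[2L], d[3L]))
  cat(sprintf("  flats: %d before + %d after, darks: %d\n", nb, na, nd))
  show(object@geometry)
})

setMethod("show", "Sinogram", function(object) {
  cat(sprintf("Sinogram: %d angles x %d columns, axis %.3f, row %s\n",
              nrow(object@values), ncol(object@values), object@axisPosition,
              ifelse(is.na(object@rowIndex), "<synthetic>", object@rowIndex)))
})

setMethod("show", "ReconSlice", function(object) {
  cat(sprintf("ReconSlice: %d x %d px of %.3g m, quantity '%s'\n",
              nrow(object@values), ncol(object@values), object@pixelSize,
              object@quantity))
})

setMethod("show", "EigenFlatBasis", function(object) {
  k <- length(object@explainedVariance)
  cat(sprintf("EigenFlatBasis: %d component(s) on %d x %d px frames\n",
              k, nrow(object@meanFlat), ncol(object@meanFlat)))
  if (k)
    cat("  explained variance:",
        paste(sprintf("%.3f", object@explainedVariance), collapse = " "), "\n")
})

setMethod("show", "RetrievalConfig", function(object) {
  cat(sprintf(
    "RetrievalConfig: %s (delta/beta %.4g, reg %.3g, clamp %.3g, pad %d)\n",
    object@method, object@deltaBetaRatio, object@regularization,
    object@responseClamp, object@padding))
})

## ---------------------------------------------------------------------------
## accessors
## ---------------------------------------------------------------------------

#' @rdname pbitomo-accessors
#' @export
setMethod("values", "Sinogram", function(x) x@values)
#' @rdname pbitomo-accessors
#' @export
setMethod("values", "ReconSlice", function(x) x@values)
#' @rdname pbitomo-accessors
#' @export
setMethod("scanGeometry", "ProjectionSet", function(x) x@geometry)
#' @rdname pbitomo-accessors
#' @export
setMethod("angles", "Geometry", function(x) x@angles)
#' @rdname pbitomo-accessors
#' @export
setMethod("angles", "Sinogram", function(x) x@angles)
#' @rdname pbitomo-accessors
#' @export
setMethod("angles", "ProjectionSet", function(x) x@geometry@angles)
#' @rdname pbitomo-accessors
#' @export
setMethod("pixelSize", "Geometry", function(x) x@pixelSize)
#' @rdname pbitomo-accessors
#' @export
setMethod("pixelSize", "Sinogram", function(x) x@pixelSize)
#' @rdname pbitomo-accessors
#' @export
setMethod("pixelSize", "ReconSlice", function(x) x@pixelSize)
#' @rdname pbitomo-accessors
#' @export
setMethod("pixelSize", "RefractiveMap", function(x) x@pixelSize)
#' @rdname pbitomo-accessors
#' @export
setMethod("axisPosition", "Geometry", function(x) x@axisPosition)
#' @rdname pbitomo-accessors
#' @export
setMethod("axisPosition", "Sinogram", function(x) x@axisPosition)
#' @rdname pbitomo-accessors
#' @export
setMethod("axisPosition<-", "Geometry", function(x, value) {
  x@axisPosition <- as.numeric(value); validObject(x); x
})
#' @rdname pbitomo-accessors
#' @export
setMethod("axisPosition<-", "Sinogram", function(x, value) {
  x@axisPosition <- as.numeric(value); validObject(x); x
})
#' @rdname pbitomo-accessors
#' @export
setMethod("wavelength", "Geometry", function(x) x@wavelength)
#' @rdname pbitomo-accessors
#' @export
setMethod("energy", "Geometry", function(x) x@energy)
#' @rdname pbitomo-accessors
#' @export
setMethod("distance", "Geometry", function(x) x@distance)
#' @rdname pbitomo-accessors
#' @export
setMethod("scanMode", "Geometry", function(x) x@scanMode)
#' @rdname pbitomo-accessors
#' @export
setMethod("projections", "ProjectionSet", function(x) x@projections)
#' @rdname pbitomo-accessors
#' @param which for `flats()`: `"all"`, `"before"` or `"after"`.
#' @param ... passed to methods.
#' @export
setMethod("flats", "ProjectionSet", function(x, which = c("all", "before", "after")) {
  which <- match.arg(which)
  b <- x@flatsBefore; a <- x@flatsAfter
  if (which == "before") return(b)
  if (which == "after") return(a)
  if (length(a) == 0L) return(b)
  if (length(b) == 0L) return(a)
  out <- array(0, dim = c(dim(b)[1L] + dim(a)[1L], dim(b)[2L], dim(b)[3L]))
  out[seq_len(dim(b)[1L]), , ] <- b
  out[dim(b)[1L] + seq_len(dim(a)[1L]), , ] <- a
  out
})
#' @rdname pbitomo-accessors
#' @export
setMethod("darks", "ProjectionSet", function(x) x@darks)
#' @rdname pbitomo-accessors
#' @export
setMethod("nProjections", "ProjectionSet", function(x) dim(x@projections)[1L])
#' @rdname pbitomo-accessors
#' @export
setMethod("quantity", "ReconSlice", function(x) x@quantity)
#' @rdname pbitomo-accessors
#' @export
setMethod("components", "EigenFlatBasis", function(x) x@components)
#' @rdname pbitomo-accessors
#' @export
setMethod("explainedVariance", "EigenFlatBasis", function(x) x@explainedVariance)
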