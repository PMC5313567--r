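#' @include AllClasses.R
NULL

#' Convert photon energy to wavelength
#'
#' \code{lambda = hc / E} with CODATA values of \code{h} and \code{c}
#' (\code{hc = 1.239841984e-9} keV m). Strictly decreasing in energy;
#' \code{wavelengthToEnergy()} is its exact inverse.
#'
#' @param energy photon energy, keV; must be positive.
#' @return wavelength, m.
#' @examples
#' energyToWavelength(40)   # ~3.0996e-11 m
#' @export
energyToWavelength <- function(energy) {
  if (any(!is.finite(energy)) || any(energy <= 0))
    stop("'energy' must be positive (keV)")
  .hc_keV_m / energy
}

#' @rdname energyToWavelength
#' @param wavelength wavelength, m; must be positive.
#' @export
wavelengthToEnergy <- function(wavelength) {
  if (any(!is.finite(wavelength)) || any(wavelength <= 0))
    stop("'wavelength' must be positive (m)")
  .hc_keV_m / wavelength
}

#' Fresnel number of a feature in a PBI geometry
#'
#' \code{N_F = a^2 / (lambda d)}: the standard regime diagnostic for
#' propagation-based imaging. Large values mean near-contact imaging
#' (negligible diffraction), values around or below 1 the edge-enhancement
#' / holographic regimes.
#'
#' @param featureSize characteristic feature size \code{a}, m.
#' @param geometry a [Geometry-class].
#' @return Fresnel number (dimensionless); \code{Inf} with attribute
#'   \code{regime = "contact"} when the propagation distance is zero.
#' @export
fresnelNumber <- function(featureSize, geometry) {
  stopifnot(is(geometry, "Geometry"))
  if (any(featureSize <= 0)) stop("'featureSize' must be positive (m)")
  if (geometry@distance == 0) {
    out <- Inf
    attr(out, "regime") <- "contact"
    return(out)
  }
  featureSize^2 / (geometry@wavelength * geometry@distance)
}

#' Construct an acquisition geometry
#'
#' @param energy photon energy, keV.
#' @param pixelSize detector pixel size, m.
#' @param distance sample-to-detector distance, m.
#' @param angles ordered rotation angles, degrees, strictly increasing.
#' @param detectorWidth detector width, pixels.
#' @param axisPosition rotation-axis column (fractional, 0-based,
#'   pixel-center convention); defaults to the detector center.
#' @param scanMode \code{"half_turn_180"} (default) or
#'   \code{"full_turn_360_offset"} for half-acquisition scans.
#' @return a validated [Geometry-class].
#' @examples
#' g <- geometry(40, 3.05e-6, 2.2, seq(0, 179.5, by = 0.5), 256L)
#' fresnelNumber(3.05e-6, g)
#' @export
geometry <- function(energy, pixelSize, distance, angles, detectorWidth,
                     axisPosition = (detectorWidth - 1) / 2,
                     scanMode = c("half_turn_180", "full_turn_360_offset")) {
  scanMode <- match.arg(scanMode)
  new("Geometry",
      energy = as.numeric(energy),
      wavelength = energyToWavelength(energy),
      pixelSize = as.numeric(pixelSize),
      distance = as.numeric(distance),
      angles = as.numeric(angles),
      axisPosition = as.numeric(axisPosition),
      detectorWidth = as.integer(detectorWidth),
      scanMode = scanMode)
}

#' Construct a refractive-index map pair
#'
#' @param delta,beta matching 2-D maps of the refractive-index decrement
#'   and absorption index.
#' @param pixelSize grid pixel size, m.
#' @return a validated [RefractiveMap-class].
#' @export
refractiveMap <- function(delta, beta, pixelSize) {
  new("RefractiveMap", delta = delta, beta = beta,
      pixelSize = as.numeric(pixelSize))
}

#' Construct a projection set
#'
#' @param projections n_proj x height x width array of detector counts.
#' @param flatsBefore,flatsAfter,darks frame stacks (n x h x w arrays);
#'   \code{flatsAfter} may be empty.
#' @param geometry a [Geometry-class] whose angle count matches.
#' @return a validated [ProjectionSet-class].
#' @export
projectionSet <- function(projections, flatsBefore, darks, geometry,
                          flatsAfter = array(0, c(0, 0, 0))) {
  storage.mode(projections) <- "double"
  storage.mode(flatsBefore) <- "double"
  storage.mode(flatsAfter) <- "double"
  storage.mode(darks) <- "double"
  new("ProjectionSet", projections = projections, flatsBefore = flatsBefore,
      flatsAfter = flatsAfter, darks = darks, geometry = geometry)
}

#' Construct a sinogram
#'
#' @param values n_angles x width matrix of (usually flat-corrected)
#'   detector readings or line integrals.
#' @param angles rotation angles, degrees, one per row.
#' @param axisPosition rotation-axis column, fractional 0-based pixels.
#' @param pixelSize detector pixel size, m.
#' @param rowIndex detector row of origin (0-based); NA for synthetic data.
#' @return a validated [Sinogram-class].
#' @export
sinogram <- function(values, angles, axisPosition = (ncol(values) - 1) / 2,
                     pixelSize, rowIndex = NA_integer_) {
  new("Sinogram", values = values, angles = as.numeric(angles),
      axisPosition = as.numeric(axisPosition),
      pixelSize = as.numeric(pixelSize), rowIndex = as.integer(rowIndex))
}

#' Construct a reconstructed slice
#'
#' @param values square 2-D map.
#' @param pixelSize slice pixel size, m.
#' @param quantity one of \code{"attenuation_coefficient"}, \code{"delta"},
#'   \code{"phase"}.
#' @return a validated [ReconSlice-class].
#' @export
reconSlice <- function(values, pixelSize,
                       quantity = c("attenuation_coefficient", "delta", "phase")) {
  quantity <- match.arg(quantity)
  new("ReconSlice", values = values, pixelSize = as.numeric(pixelSize),
      quantity = quantity)
}

#' Construct a phase-retrieval configuration
#'
#' @param method \code{"paganin"} (TIE-Hom), \code{"ctf_pure_phase"} or
#'   \code{"projected_ctf"}.
#' @param deltaBetaRatio assumed delta/beta ratio of the sample (Paganin).
#' @param regularization small positive constant regularizing the CTF
#'   inversion where the sine response vanishes.
#' @param responseClamp chi value past which the projected-CTF response is
#'   clamped (default pi/2, the first response maximum).
#' @param padding symmetric padding in pixels applied before the DFT.
#' @return a validated [RetrievalConfig-class].
#' @export
retrievalConfig <- function(method = c("paganin", "ctf_pure_phase", "projected_ctf"),
                            deltaBetaRatio = 100,
                            regularization = 1e-4,
                            responseClamp = pi / 2,
                            padding = 128L) {
  method <- match.arg(method)
  new("RetrievalConfig", method = method,
      deltaBetaRatio = as.numeric(deltaBetaRatio),
      regularization = as.numeric(regularization),
      responseClamp = as.numeric(responseClamp),
      padding = as.integer(padding))
}

#' Serialize a geometry to a flat key-value list (and back)
#'
#' The representation used in workflow parameter files: scalar fields plus
#' the explicit angle list.
#'
#' @param g a [Geometry-class].
#' @return \code{geometryToList()}: a named list of plain R values;
#'   \code{geometryFromList()}: a [Geometry-class].
#' @export
geometryToList <- function(g) {
  stopifnot(is(g, "Geometry"))
  list(energy = g@energy, pixel_size = g@pixelSize, distance = g@distance,
       angles = g@angles, axis_position = g@axisPosition,
       detector_width = as.integer(g@detectorWidth), scan_mode = g@scanMode)
}

#' @rdname geometryToList
#' @param x a named list as produced by \code{geometryToList()}.
#' @export
geometryFromList <- function(x) {
  need <- c("energy", "pixel_size", "distance", "angles", "detector_width")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("geometry section is missing field(s): ", paste(miss, collapse = ", "))
  geometry(energy = x$energy, pixelSize = x$pixel_size, distance = x$distance,
           angles = unlist(x$angles), detectorWidth = x$detector_width,
           axisPosition = if (!is.null(x$axis_position)) x$axis_position
                          else (x$detector_width - 1) / 2,
           scanMode = if (!is.null(x$scan_mode)) x$scan_mode else "half_turn_180")
}
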