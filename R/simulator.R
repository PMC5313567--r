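#' @include utils_fft.R
NULL

#' Specify one ellipse of a refractive phantom
#'
#' Phantoms are additive superpositions of ellipses: where ellipses
#' overlap, their delta and beta increments add. All lengths in meters,
#' rotation in degrees (counter-clockwise).
#'
#' @param centerX,centerY ellipse center, m.
#' @param semiAxisA,semiAxisB semi-axes, m; positive.
#' @param rotation rotation of axis A from the x axis, degrees.
#' @param delta,beta additive refractive increments of the ellipse.
#' @return an object of class \code{"EllipseSpec"}.
#' @export
ellipseSpec <- function(centerX = 0, centerY = 0, semiAxisA, semiAxisB,
                        rotation = 0, delta = 0, beta = 0) {
  ## increments may be negative (cavities); total beta >= 0 is enforced
  ## on the rasterized RefractiveMap
  if (semiAxisA <= 0 || semiAxisB <= 0) stop("semi-axes must be positive")
  structure(list(centerX = centerX, centerY = centerY,
                 semiAxisA = semiAxisA, semiAxisB = semiAxisB,
                 rotation = rotation, delta = delta, beta = beta),
            class = "EllipseSpec")
}

.checkEllipses <- function(ellipses) {
  if (!is.list(ellipses)) stop("'ellipses' must be a list of ellipseSpec()")
  for (e in ellipses)
    if (!inherits(e, "EllipseSpec")) stop("all entries must be ellipseSpec()")
  invisible(ellipses)
}

#' Rasterize an ellipse phantom onto a square grid
#'
#' Pixel membership is decided by the pixel-center test; the grid is
#' centered (pixel-center convention, 0-based). A warning is raised when
#' an ellipse extends beyond the inscribed circle of the grid, since its
#' projections would then be truncated at some angles.
#'
#' @param ellipses list of [ellipseSpec()] objects (may be empty).
#' @param gridSize grid side, pixels (>= 16).
#' @param pixelSize grid pixel size, m.
#' @return a [RefractiveMap-class].
#' @export
makePhantom <- function(ellipses, gridSize, pixelSize) {
  .checkEllipses(ellipses)
  gridSize <- as.integer(gridSize)
  if (gridSize < 16L) stop("'gridSize' must be at least 16")
  c0 <- (gridSize - 1) / 2
  x <- ((0:(gridSize - 1)) - c0) * pixelSize   # columns
  y <- ((0:(gridSize - 1)) - c0) * pixelSize   # rows
  delta <- matrix(0, gridSize, gridSize)
  beta <- matrix(0, gridSize, gridSize)
  rin <- gridSize / 2 * pixelSize
  X <- matrix(x, gridSize, gridSize, byrow = TRUE)
  Y <- matrix(y, gridSize, gridSize)
  for (e in ellipses) {
    reach <- sqrt(e$centerX^2 + e$centerY^2) + max(e$semiAxisA, e$semiAxisB)
    if (reach > rin)
      warning("ellipse extends beyond the inscribed circle; ",
              "projections will be truncated at some angles")
    phi <- .deg2rad(e$rotation)
    xr <- (X - e$centerX) * cos(phi) + (Y - e$centerY) * sin(phi)
    yr <- -(X - e$centerX) * sin(phi) + (Y - e$centerY) * cos(phi)
    inside <- (xr / e$semiAxisA)^2 + (yr / e$semiAxisB)^2 <= 1
    delta <- delta + e$delta * inside
    beta <- beta + e$beta * inside
  }
  refractiveMap(delta, beta, pixelSize)
}

#' Closed-form Radon transform of an ellipse phantom
#'
#' For each rotation angle and detector column, sums the exact chord
#' integrals of all ellipses: after rotating/translating the ray into the
#' ellipse frame, a ray at signed offset \code{s} from the ellipse center
#' intersects chord \code{2 a b sqrt(rho^2 - s^2) / rho^2} where
#' \code{rho^2 = a^2 cos^2 t + b^2 sin^2 t} and \code{t} is the angle in
#' the ellipse frame. Detector columns are placed at
#' \code{(j - axisPosition) * pixelSize}.
#'
#' @param ellipses list of [ellipseSpec()] objects.
#' @param geometry a [Geometry-class] (angles, detector width, axis).
#' @param which which increment to integrate: \code{"delta"},
#'   \code{"beta"}, or \code{"thickness"} (indicator value 1 per ellipse,
#'   i.e. projected material thickness).
#' @return a [Sinogram-class] of line integrals (units: m times the
#'   integrated quantity).
#' @export
analyticSinogram <- function(ellipses, geometry,
                             which = c("delta", "beta", "thickness")) {
  .checkEllipses(ellipses)
  which <- match.arg(which)
  stopifnot(is(geometry, "Geometry"))
  th <- .deg2rad(geometry@angles)
  W <- geometry@detectorWidth
  s <- ((0:(W - 1)) - geometry@axisPosition) * geometry@pixelSize
  out <- matrix(0, length(th), W)
  for (e in ellipses) {
    v <- switch(which, delta = e$delta, beta = e$beta, thickness = 1)
    if (v == 0) next
    t <- th - .deg2rad(e$rotation)
    rho2 <- (e$semiAxisA * cos(t))^2 + (e$semiAxisB * sin(t))^2
    scen <- e$centerX * cos(th) + e$centerY * sin(th)
    srel <- outer(-scen, s, `+`)            # s - center offset, per angle
    under <- pmax(rho2 - srel^2, 0)
    out <- out + 2 * e$semiAxisA * e$semiAxisB * v * sqrt(under) / rho2
  }
  sinogram(out, geometry@angles, geometry@axisPosition, geometry@pixelSize)
}

#' Fresnel free-space propagation of a projected wavefield
#'
#' Builds the complex transmittance
#' \code{u = exp(-(2 pi / lambda) B) * exp(-i (2 pi / lambda) D)} from the
#' delta and beta line integrals \code{D} and \code{B}, applies the
#' paraxial free-space propagator \code{exp(-i pi lambda d |f|^2)} in the
#' discrete Fourier domain (\code{f} in cycles per unit length), and
#' returns the intensity \code{|u_d|^2} for unit incident intensity.
#' Boundaries are periodic; optional symmetric padding suppresses
#' wrap-around.
#'
#' @param deltaProjection,betaProjection matching 2-D line-integral maps
#'   (m); e.g. rows of [analyticSinogram()] results.
#' @param geometry a [Geometry-class] (wavelength, pixel size, distance).
#' @param padding symmetric padding in pixels (default 0: periodic).
#' @return intensity image, same shape as the input.
#' @export
propagate <- function(deltaProjection, betaProjection, geometry, padding = 0L) {
  stopifnot(is(geometry, "Geometry"))
  if (!identical(dim(deltaProjection), dim(betaProjection)))
    stop("delta and beta projections must have the same shape")
  if (any(!is.finite(deltaProjection)) || any(!is.finite(betaProjection)))
    stop("non-finite values in input projections")
  if (geometry@distance < 0) stop("propagation distance must be non-negative")
  h <- nrow(deltaProjection); w <- ncol(deltaProjection)
  k <- 2 * pi / geometry@wavelength
  D <- .padSym(deltaProjection, padding)
  B <- .padSym(betaProjection, padding)
  u <- matrix(exp(complex(real = -k * B, imaginary = -k * D)),
              nrow(B), ncol(B))
  if (geometry@distance > 0) {
    f2 <- .freqSq(nrow(u), ncol(u), geometry@pixelSize)
    prop <- exp(-1i * pi * geometry@wavelength * geometry@distance * f2)
    u <- .ifft2(.fft2(u) * prop)
  }
  intensity <- Mod(u)^2
  .cropSym(intensity, padding, h, w)
}

#' Detector/beamline corruption model for simulated scans
#'
#' Describes how ideal intensities become detector counts: a per-pixel
#' multiplicative gain map (fixed stripes and bright spots, the source of
#' ring artifacts), a low-rank beam-drift model (a few spatial images
#' modulated by smooth temporal weights, emulating source/monochromator
#' instability over a long scan), Poisson photon statistics at a given
#' expected count, and an additive dark level.
#'
#' @param gainMap per-pixel multiplicative gain (h x w), strictly positive.
#' @param driftImages k x h x w array of spatial drift components (may be
#'   empty: `array(0, c(0, h, w))`).
#' @param driftWeights k x T matrix of temporal weights; T must equal
#'   n_flats_before + n_projections + n_flats_after of the simulated scan.
#' @param photonCount expected counts at unit transmission; positive.
#' @param darkLevel additive offset counts.
#' @param seed RNG seed; every corruption is reproducible from it.
#' @param noise logical; disable to obtain the deterministic expectation.
#' @return an object of class \code{"CorruptionModel"}.
#' @export
corruptionModel <- function(gainMap, driftImages, driftWeights,
                            photonCount, darkLevel = 0, seed = 1L,
                            noise = TRUE) {
  if (any(gainMap <= 0)) stop("'gainMap' must be strictly positive")
  if (photonCount <= 0) stop("'photonCount' must be positive")
  k <- if (length(driftImages)) dim(driftImages)[1L] else 0L
  if (k > 0L) {
    stopifnot(is.matrix(driftWeights), nrow(driftWeights) == k)
    if (!identical(dim(driftImages)[2:3], dim(gainMap)))
      stop("drift images must share the gain-map shape")
  }
  structure(list(gainMap = gainMap, driftImages = driftImages,
                 driftWeights = driftWeights, photonCount = photonCount,
                 darkLevel = darkLevel, seed = as.integer(seed),
                 noise = isTRUE(noise)),
            class = "CorruptionModel")
}

.driftField <- function(model, t) {
  g <- model$gainMap * 0 + 1
  k <- if (length(model$driftImages)) dim(model$driftImages)[1L] else 0L
  if (k == 0L) return(g)
  for (j in seq_len(k))
    g <- g + model$driftWeights[j, t] * model$driftImages[j, , ]
  g
}

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Apply a corruption model to a clean intensity stack
#'
#' Frame \code{t} of the time series (flats before, then projections,
#' then flats after) becomes
#' \code{Poisson(photonCount * gain * drift(t) * clean_t) + darkLevel};
#' flat frames use unit transmission. Dark frames are Poisson draws around
#' the dark level. Identical seeds yield identical datasets.
#'
#' @param cleanStack n_proj x h x w array of ideal intensities (unit
#'   incident beam).
#' @param model a [corruptionModel()].
#' @param geometry a [Geometry-class] matching the stack.
#' @param nFlatsBefore,nFlatsAfter,nDarks frame counts to synthesize.
#' @return a [ProjectionSet-class] of detector counts.
#' @export
corrupt <- function(cleanStack, model, geometry,
                    nFlatsBefore = 8L, nFlatsAfter = 0L, nDarks = 2L) {
  stopifnot(inherits(model, "CorruptionModel"), is(geometry, "Geometry"))
  np <- dim(cleanStack)[1L]
  h <- dim(cleanStack)[2L]; w <- dim(cleanStack)[3L]
  nT <- nFlatsBefore + np + nFlatsAfter
  k <- if (length(model$driftImages)) dim(model$driftImages)[1L] else 0L
  if (k > 0L && ncol(model$driftWeights) != nT)
    stop("drift weight series length must equal n_flats + n_projections (",
         nT, ")")
  one <- matrix(1, h, w)
  frame <- function(clean, t) {
    expected <- model$photonCount * model$gainMap * .driftField(model, t) * clean
    if (model$noise)
      matrix(rpois(h * w, expected + model$darkLevel), h, w)
    else
      expected + model$darkLevel
  }
  .withSeed(model$seed, {
    fb <- array(0, c(nFlatsBefore, h, w))
    for (i in seq_len(nFlatsBefore)) fb[i, , ] <- frame(one, i)
    proj <- array(0, c(np, h, w))
    for (i in seq_len(np)) proj[i, , ] <- frame(cleanStack[i, , ], nFlatsBefore + i)
    fa <- array(0, c(nFlatsAfter, h, w))
    for (i in seq_len(nFlatsAfter)) fa[i, , ] <- frame(one, nFlatsBefore + np + i)
    dk <- array(0, c(nDarks, h, w))
    if (nDarks > 0L)
      for (i in seq_len(nDarks))
        dk[i, , ] <- if (model$noise && model$darkLevel > 0)
          matrix(rpois(h * w, model$darkLevel), h, w)
        else matrix(model$darkLevel, h, w)
    projectionSet(proj, flatsBefore = fb, darks = dk, geometry = geometry,
                  flatsAfter = fa)
  })
}

.simulateScan <- function(ellipses, geometry, height, corruption = NULL,
                          padding = 0L,
                          nFlatsBefore = 8L, nFlatsAfter = 0L, nDarks = 2L) {
  .checkEllipses(ellipses)
  sd_ <- analyticSinogram(ellipses, geometry, "delta")@values
  sb_ <- analyticSinogram(ellipses, geometry, "beta")@values
  np <- length(geometry@angles)
  w <- geometry@detectorWidth
  clean <- array(0, c(np, height, w))
  for (i in seq_len(np)) {
    irow <- propagate(matrix(sd_[i, ], 1L), matrix(sb_[i, ], 1L), geometry,
                      padding = padding)
    clean[i, , ] <- matrix(irow, height, w, byrow = TRUE)
  }
  if (is.null(corruption)) {
    one <- array(1, c(1L, height, w))
    zero <- array(0, c(1L, height, w))
    projectionSet(clean, flatsBefore = one, darks = zero, geometry = geometry)
  } else {
    corrupt(clean, corruption, geometry,
            nFlatsBefore = nFlatsBefore, nFlatsAfter = nFlatsAfter,
            nDarks = nDarks)
  }
}

#' Simulate a parallel-beam PBI scan of an ellipse phantom
#'
#' Forward model: exact closed-form line integrals of the phantom at each
#' angle/column, Fresnel propagation to the detector plane, extrusion to
#' the requested projection height (the phantom is z-invariant), then
#' optional detector/beamline corruption. Without corruption the returned
#' set carries ideal unit flats and zero darks.
#'
#' @param ellipses list of [ellipseSpec()] objects.
#' @param geometry a [Geometry-class]; for
#'   [simulateHalfAcquisition()] the scan mode must be
#'   \code{"full_turn_360_offset"}, the angles must span a full turn and
#'   \code{axisPosition} holds the (known, off-center) rotation axis.
#' @param height projection height, pixels.
#' @param corruption optional [corruptionModel()].
#' @param padding padding passed to [propagate()].
#' @param nFlatsBefore,nFlatsAfter,nDarks frame counts when corrupting.
#' @return a [ProjectionSet-class].
#' @export
simulateParallelScan <- function(ellipses, geometry, height = 1L,
                                 corruption = NULL, padding = 0L,
                                 nFlatsBefore = 8L, nFlatsAfter = 0L,
                                 nDarks = 2L) {
  .simulateScan(ellipses, geometry, height, corruption, padding,
                nFlatsBefore, nFlatsAfter, nDarks)
}

#' @rdname simulateParallelScan
#' @export
simulateHalfAcquisition <- function(ellipses, geometry, height = 1L,
                                    corruption = NULL, padding = 0L,
                                    nFlatsBefore = 8L, nFlatsAfter = 0L,
                                    nDarks = 2L) {
  stopifnot(is(geometry, "Geometry"))
  if (geometry@scanMode != "full_turn_360_offset")
    stop("half-acquisition simulation requires scan mode 'full_turn_360_offset'")
  if (geometry@axisPosition < 0 || geometry@axisPosition > geometry@detectorWidth - 1)
    stop("rotation axis must lie inside the detector")
  .simulateScan(ellipses, geometry, height, corruption, padding,
                nFlatsBefore, nFlatsAfter, nDarks)
}

#' Smooth low-rank beam-drift components for a simulated scan
#'
#' Convenience builder of a physically plausible drift model: each spatial
#' component is a broad, smooth intensity pattern (low-order polynomial
#' ramp/vignetting shapes), each temporal weight series a slow random walk
#' smoothed over the scan, scaled to a given relative amplitude.
#'
#' @param height,width frame shape, pixels.
#' @param nTimes length of the temporal series (flats + projections).
#' @param nComponents number of drift components (default 2).
#' @param amplitude peak relative intensity excursion per component.
#' @param seed RNG seed.
#' @return list with elements \code{images} (k x h x w) and
#'   \code{weights} (k x nTimes), ready for [corruptionModel()].
#' @export
makeDriftModel <- function(height, width, nTimes, nComponents = 2L,
                           amplitude = 0.03, seed = 1L) {
  .withSeed(seed, {
    yy <- seq(-1, 1, length.out = height)
    xx <- seq(-1, 1, length.out = width)
    shapes <- list(
      outer(rep(1, height), xx),                       # horizontal ramp
      outer(yy, rep(1, width)),                        # vertical ramp
      outer(yy, xx),                                   # diagonal saddle
      1 - outer(yy^2, rep(1, width)) - outer(rep(1, height), xx^2) / 2
    )
    k <- as.integer(nComponents)
    imgs <- array(0, c(k, height, width))
    for (j in seq_len(k)) {
      s <- shapes[[(j - 1L) %% length(shapes) + 1L]]
      imgs[j, , ] <- s / max(abs(s))
    }
    wts <- matrix(0, k, nTimes)
    for (j in seq_len(k)) {
      walk <- cumsum(rnorm(nTimes))
      walk <- .movAvg(walk, max(3L, 2L * (nTimes %/% 20L) + 1L))
      walk <- walk - mean(walk)
      wts[j, ] <- amplitude * walk / max(abs(walk))
    }
    list(images = imgs, weights = wts)
  })
}

#' Build and run a simulation from a parameter-file specification
#'
#' Interprets the `simulate` section of a workflow parameter file: a
#' geometry (same flat key-value form as [geometryToList()]), a list of
#' ellipses, the projection height, frame counts, and an optional
#' corruption block with gain stripes and low-rank beam drift. Writing
#' the result through [writeProjectionSet()] yields a dataset any
#' workflow can consume.
#'
#' @param sim named list, typically `parseWorkflow(...)$simulate` or the
#'   `simulate:` section of a YAML file: fields `geometry`, `ellipses`
#'   (list of lists with the [ellipseSpec()] fields in snake_case),
#'   `height`, `padding`, `n_flats_before`, `n_flats_after`, `n_darks`,
#'   and optional `corruption` with `photon_count`, `dark_level`, `seed`,
#'   `gain_stripes` (`n`, `min`, `max`) and `drift` (`n_components`,
#'   `amplitude`).
#' @param outputPath optional dataset directory to write.
#' @param layout layout used when writing; see [datasetLayout()].
#' @return the simulated [ProjectionSet-class], invisibly when written.
#' @export
simulateFromSpec <- function(sim, outputPath = NULL, layout = datasetLayout()) {
  if (is.null(sim$geometry)) stop("simulate spec needs a 'geometry' section")
  g <- geometryFromList(sim$geometry)
  if (is.null(sim$ellipses) || !length(sim$ellipses))
    stop("simulate spec needs a non-empty 'ellipses' list")
  ell <- lapply(sim$ellipses, function(e) ellipseSpec(
    centerX = e$center_x %||% 0, centerY = e$center_y %||% 0,
    semiAxisA = e$semi_axis_a, semiAxisB = e$semi_axis_b,
    rotation = e$rotation %||% 0, delta = e$delta %||% 0,
    beta = e$beta %||% 0))
  height <- as.integer(sim$height %||% 1L)
  pad <- as.integer(sim$padding %||% 32L)
  nFB <- as.integer(sim$n_flats_before %||% 8L)
  nFA <- as.integer(sim$n_flats_after %||% 0L)
  nDK <- as.integer(sim$n_darks %||% 2L)
  cm <- NULL
  co <- sim$corruption
  if (!is.null(co)) {
    W <- g@detectorWidth
    seed <- as.integer(co$seed %||% 1L)
    gain <- matrix(1, height, W)
    gs <- co$gain_stripes
    if (!is.null(gs)) {
      gain <- .withSeed(seed, {
        cols <- sample(W, gs$n %||% 5L)
        gain[, cols] <- gain[, cols] *
          (1 + runif(length(cols), gs$min %||% 0.01, gs$max %||% 0.03))
        gain
      })
    }
    dr <- co$drift
    nT <- nFB + length(g@angles) + nFA
    if (!is.null(dr)) {
      dm <- makeDriftModel(height, W, nT,
                           nComponents = as.integer(dr$n_components %||% 2L),
                           amplitude = dr$amplitude %||% 0.03,
                           seed = seed + 1L)
      imgs <- dm$images; wts <- dm$weights
    } else {
      imgs <- array(0, c(0, height, W)); wts <- matrix(0, 0, 0)
    }
    cm <- corruptionModel(gain, imgs, wts,
                          photonCount = co$photon_count %||% 1e5,
                          darkLevel = co$dark_level %||% 0,
                          seed = seed,
                          noise = !isFALSE(co$noise))
  }
  ps <- if (g@scanMode == "full_turn_360_offset")
    simulateHalfAcquisition(ell, g, height = height, corruption = cm,
                            padding = pad, nFlatsBefore = nFB,
                            nFlatsAfter = nFA, nDarks = nDK)
  else
    simulateParallelScan(ell, g, height = height, corruption = cm,
                         padding = pad, nFlatsBefore = nFB,
                         nFlatsAfter = nFA, nDarks = nDK)
  if (!is.null(outputPath)) {
    writeProjectionSet(ps, outputPath, layout)
    return(invisible(ps))
  }
  ps
}

`%||%` <- function(a, b) if (is.null(a)) b else a
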