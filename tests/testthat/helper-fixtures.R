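# Shared fixtures: all inputs are generated in code, deterministically.

PX <- 3.05e-6   # detector pixel size used throughout, m

stdGeometry <- function(nAngles = 180L, width = 128L, distance = 2.2,
                        energy = 40, span = 180, ...) {
  geometry(energy, PX, distance,
           seq(0, span - span / nAngles, length.out = nAngles), width, ...)
}

# three-ellipse soft-tissue-like phantom (body, inclusion, cavity); sized
# for the ~170-px half-acquisition field of view at 3.05 um pixels
softPhantom <- function(ratio = 400) {
  d1 <- 1.2e-7; d2 <- 8e-8; d3 <- -5e-8
  list(
    ellipseSpec(centerX = -1e-5, semiAxisA = 1.5e-4, semiAxisB = 1.2e-4,
                rotation = 20, delta = d1, beta = d1 / ratio),
    ellipseSpec(centerX = 5e-5, centerY = 3e-5, semiAxisA = 4e-5,
                semiAxisB = 2.5e-5, rotation = -30, delta = d2, beta = d2 / ratio),
    ellipseSpec(centerX = -6e-5, centerY = -4e-5, semiAxisA = 2.5e-5,
                semiAxisB = 3.5e-5, delta = d3, beta = d3 / ratio)
  )
}

# independent brute-force line-integral oracle: sample the rasterized map
# along each ray with bilinear interpolation and a fine step, then sum.
gridLineIntegrals <- function(img, pixelSize, anglesDeg, axisPosition,
                              detectorWidth, step = 0.25) {
  n <- nrow(img)
  c0 <- (n - 1) / 2
  bilinear <- function(x, y) {   # 0-based pixel coords
    x0 <- floor(x); y0 <- floor(y)
    fx <- x - x0; fy <- y - y0
    ok <- x0 >= 0 & x0 <= n - 2 & y0 >= 0 & y0 <= n - 2
    v <- numeric(length(x))
    i <- which(ok)
    # img indexed [row=y+1, col=x+1]
    v[i] <- img[cbind(y0[i] + 1, x0[i] + 1)] * (1 - fx[i]) * (1 - fy[i]) +
      img[cbind(y0[i] + 1, x0[i] + 2)] * fx[i] * (1 - fy[i]) +
      img[cbind(y0[i] + 2, x0[i] + 1)] * (1 - fx[i]) * fy[i] +
      img[cbind(y0[i] + 2, x0[i] + 2)] * fx[i] * fy[i]
    v
  }
  out <- matrix(0, length(anglesDeg), detectorWidth)
  tgrid <- seq(-n / sqrt(2), n / sqrt(2), by = step)
  for (ia in seq_along(anglesDeg)) {
    th <- anglesDeg[ia] * pi / 180
    co <- cos(th); si <- sin(th)
    for (j in seq_len(detectorWidth)) {
      s <- (j - 1) - axisPosition
      # ray: points with x cos + y sin = s, param t along (-sin, cos)
      xs <- s * co - tgrid * si + c0
      ys <- s * si + tgrid * co + c0
      out[ia, j] <- sum(bilinear(xs, ys)) * step * pixelSize
    }
  }
  out
}

relL2 <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))
rmse <- function(a, b) sqrt(mean((a - b)^2))

# weak pure-phase difference-of-Gaussians map: zero mean, band-limited
dogPhase <- function(n = 256L, amplitude = 0.005, s1 = 4, s2 = 6) {
  x <- (0:(n - 1)) - (n - 1) / 2
  X <- matrix(x, n, n, byrow = TRUE); Y <- matrix(x, n, n)
  g <- function(s) exp(-(X^2 + Y^2) / (2 * s^2))
  phi0 <- g(s1) - (s1^2 / s2^2) * g(s2)
  amplitude * phi0 / max(abs(phi0))
}

# corrupted half-acquisition dataset matching the long-scan conditions the
# workflow benchmarks use (stripes + low-rank drift + Poisson noise)
halfAcqDataset <- function(height = 12L, W = 128L, photonCount = 1e6,
                           seed = 13L, axisOffset = 45.25) {
  angs360 <- seq(0, 359, 1)
  axisTrue <- (W - 1) / 2 + axisOffset
  g <- geometry(40, PX, 2.2, angs360, W, axisPosition = axisTrue,
                scanMode = "full_turn_360_offset")
  ell <- softPhantom()
  nFB <- 30L; nFA <- 30L
  nT <- nFB + length(angs360) + nFA
  drift <- makeDriftModel(height, W, nT, nComponents = 2L,
                          amplitude = 0.03, seed = 21L)
  gain <- matrix(1, height, W)
  set.seed(9)
  sc <- sample(W, 7)
  gain[, sc] <- gain[, sc] * (1 + runif(7, 0.01, 0.03))
  cm <- corruptionModel(gain, drift$images, drift$weights,
                        photonCount = photonCount, darkLevel = 10,
                        seed = seed)
  ps <- simulateHalfAcquisition(ell, g, height = height, corruption = cm,
                                padding = 32L, nFlatsBefore = nFB,
                                nFlatsAfter = nFA, nDarks = 4L)
  list(ps = ps, ellipses = ell, axisTrue = axisTrue, geometry = g)
}
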