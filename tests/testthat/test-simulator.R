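test_that("phantom rasterization matches analytic areas and is additive", {
  expect_equal(makePhantom(list(), 32, PX)@delta, matrix(0, 32, 32))
  # centered disk: pixel count vs analytic area within 2% at 256^2
  r <- 1e-4
  ph <- makePhantom(list(ellipseSpec(semiAxisA = r, semiAxisB = r,
                                     delta = 1e-7)), 256, PX)
  area_px <- sum(ph@delta > 0)
  expect_equal(area_px, pi * r^2 / PX^2, tolerance = 0.02)
  # overlapping ellipses add their increments
  e1 <- ellipseSpec(semiAxisA = 8e-5, semiAxisB = 8e-5, delta = 1e-7, beta = 1e-9)
  e2 <- ellipseSpec(centerX = 2e-5, semiAxisA = 6e-5, semiAxisB = 6e-5,
                    delta = 3e-8, beta = 5e-10)
  ph2 <- makePhantom(list(e1, e2), 128, PX)
  expect_equal(max(ph2@delta), 1.3e-7)
  expect_equal(max(ph2@beta), 1.5e-9)
  expect_warning(makePhantom(list(ellipseSpec(centerX = 3e-4,
                                              semiAxisA = 1e-4,
                                              semiAxisB = 1e-4,
                                              delta = 1)), 64, PX),
                 "inscribed circle")
})

test_that("analytic ellipse sinogram equals chord lengths and the grid oracle", {
  r <- 1e-4; v <- 1e-7
  W <- 129L  # odd width: center column passes through the origin
  g <- geometry(40, PX, 2.2, c(0, 45, 90), W)
  sg <- analyticSinogram(list(ellipseSpec(semiAxisA = r, semiAxisB = r,
                                          delta = v)), g, "delta")
  # ray through the disk center: chord 2 r v, at every angle
  expect_equal(values(sg)[, 65], rep(2 * r * v, 3), tolerance = 1e-12)
  # rays beyond the radius: exactly zero
  far <- abs(((0:(W - 1)) - 64) * PX) > r
  expect_true(all(values(sg)[, far] == 0))
  # vs the independent grid-sampling line-integral oracle
  ell <- list(ellipseSpec(semiAxisA = 2.2e-4, semiAxisB = 1.6e-4,
                          rotation = 25, delta = 1e-7),
              ellipseSpec(centerX = 6e-5, centerY = -4e-5, semiAxisA = 6e-5,
                          semiAxisB = 4e-5, delta = 5e-8))
  g2 <- stdGeometry(nAngles = 24L, width = 256L)
  ph <- makePhantom(ell, 256, PX)
  ana <- values(analyticSinogram(ell, g2, "delta"))
  ora <- gridLineIntegrals(ph@delta, PX, angles(g2), axisPosition(g2), 256L)
  expect_lt(relL2(ora, ana), 0.01)
})

test_that("Fresnel propagation has the exact contact and empty-beam limits", {
  g0 <- stdGeometry(distance = 0, width = 64L)
  set.seed(3)
  t_ <- matrix(abs(rnorm(32 * 64, sd = 1e-5)), 32, 64)
  B <- 1e-9 * t_; D <- 5e-7 * t_
  lam <- wavelength(g0)
  # d = 0: Beer-Lambert exactly, regardless of the phase term
  expect_equal(propagate(D, B, g0), exp(-4 * pi * B / lam), tolerance = 1e-12)
  # pure phase at d = 0: unit intensity
  expect_equal(propagate(D, 0 * B, g0), matrix(1, 32, 64), tolerance = 1e-12)
  g <- stdGeometry(width = 64L)
  # empty beam stays empty at any distance
  expect_equal(propagate(matrix(0, 32, 64), matrix(0, 32, 64), g),
               matrix(1, 32, 64), tolerance = 1e-12)
  # unitary propagator conserves the mean intensity (periodic boundaries)
  I0 <- propagate(D, B, g0); Id <- propagate(D, B, g)
  expect_equal(mean(Id), mean(I0), tolerance = 1e-6)
  expect_error(propagate(D, B[, 1:10], g), "same shape")
  expect_error(propagate(D * NA, B, g), "non-finite")
})

test_that("corruption is reproducible and has the exact noise-free limit", {
  g <- stdGeometry(nAngles = 8L, width = 32L)
  clean <- array(runif(8 * 4 * 32, 0.5, 1), c(8, 4, 32))
  cmOff <- corruptionModel(matrix(1, 4, 32), array(0, c(0, 4, 32)),
                           matrix(0, 0, 0), photonCount = 1,
                           darkLevel = 7, seed = 1, noise = FALSE)
  ps <- corrupt(clean, cmOff, g, nFlatsBefore = 2L, nDarks = 1L)
  expect_equal(projections(ps), clean + 7, tolerance = 1e-12)
  expect_equal(flats(ps)[1, , ], matrix(1 + 7, 4, 32))
  cmA <- corruptionModel(matrix(1, 4, 32), array(0, c(0, 4, 32)),
                         matrix(0, 0, 0), photonCount = 500, darkLevel = 3,
                         seed = 42)
  psA <- corrupt(clean, cmA, g, nFlatsBefore = 2L, nDarks = 2L)
  psB <- corrupt(clean, cmA, g, nFlatsBefore = 2L, nDarks = 2L)
  expect_identical(projections(psA), projections(psB))
  expect_identical(darks(psA), darks(psB))
  expect_error(corruptionModel(matrix(0, 2, 2), array(0, c(0, 2, 2)),
                               matrix(0, 0, 0), photonCount = 100),
               "strictly positive")
  expect_error(corruptionModel(matrix(1, 2, 2), array(0, c(0, 2, 2)),
                               matrix(0, 0, 0), photonCount = 0),
               "photonCount")
  # drift weight series must cover flats + projections
  dr <- makeDriftModel(4, 32, 5, nComponents = 1L)
  cmBad <- corruptionModel(matrix(1, 4, 32), dr$images, dr$weights,
                           photonCount = 10)
  expect_error(corrupt(clean, cmBad, g, nFlatsBefore = 2L), "series length")
})

test_that("gain stripes become angle-constant offsets in the sinogram", {
  g <- stdGeometry(nAngles = 40L, width = 64L)
  ell <- list(ellipseSpec(semiAxisA = 6e-5, semiAxisB = 5e-5,
                          delta = 1e-7, beta = 2e-9))
  gain <- matrix(1, 4, 64)
  cols <- c(10, 20, 30, 40, 50)
  gain[, cols] <- 1.02
  cm <- corruptionModel(gain, array(0, c(0, 4, 64)), matrix(0, 0, 0),
                        photonCount = 1, darkLevel = 0, seed = 1,
                        noise = FALSE)
  ps <- simulateParallelScan(ell, g, height = 4L, corruption = cm,
                             nFlatsBefore = 2L, nDarks = 1L, padding = 16L)
  clean <- simulateParallelScan(ell, g, height = 4L, padding = 16L)
  # flats see the same gain, so flat fielding cancels it...
  ff <- flatFieldStack(ps, "conventional")
  expect_equal(ff, flatFieldStack(clean, "conventional"), tolerance = 1e-10,
               ignore_attr = TRUE)
  # ...but a gain error present only during the scan leaves stripes
  psStripe <- clean
  psStripe@projections <- clean@projections * rep(gain, each = 40)
  ff2 <- flatFieldStack(psStripe, "conventional")
  ratio <- ff2[, 1, ] / flatFieldStack(clean, "conventional")[, 1, ]
  expect_equal(apply(ratio[, cols], 2, sd), rep(0, 5), tolerance = 1e-10)
  expect_equal(colMeans(ratio[, cols]), rep(1.02, 5), tolerance = 1e-10)
})

test_that("half-acquisition simulation is mirror-consistent and stitchable", {
  W <- 128L
  angs <- seq(0, 359, 1)
  ell <- softPhantom()
  # centered axis: rows at theta and theta+180 are mirror images
  g0 <- geometry(40, PX, 2.2, angs, W, scanMode = "full_turn_360_offset")
  ps0 <- simulateHalfAcquisition(ell, g0, height = 1L, padding = 32L)
  expect_equal(ps0@projections[1, 1, ], rev(ps0@projections[181, 1, ]),
               tolerance = 1e-6)
  # known offset is recovered by the axis estimator within 0.5 px
  axisTrue <- (W - 1) / 2 + 20
  g <- geometry(40, PX, 2.2, angs, W, axisPosition = axisTrue,
                scanMode = "full_turn_360_offset")
  ps <- simulateHalfAcquisition(ell, g, height = 8L, padding = 32L)
  st <- flatFieldStack(ps, "conventional")
  est <- estimateAxisPosition(st[1, , ], st[181, , ])
  expect_lt(abs(as.numeric(est) - axisTrue), 0.5)
  # stitched sinogram vs direct wide-detector 180-degree simulation
  sg <- extractSinogram(st, 0L, geometry = g)
  stitched <- stitchHalfAcquisition(sg, axisPosition = as.numeric(est))
  Wp <- ncol(values(stitched))
  gw <- geometry(40, PX, 2.2, angs[1:180], as.integer(Wp),
                 axisPosition = axisPosition(stitched))
  direct <- flatFieldStack(simulateParallelScan(ell, gw, height = 1L,
                                                padding = 32L),
                           "conventional")[, 1, ]
  expect_lt(rmse(values(stitched), direct) / diff(range(direct)), 0.02)
  # axis outside the detector is rejected
  gBad <- g0
  expect_error(simulateHalfAcquisition(ell, geometry(
    40, PX, 2.2, angs, W, axisPosition = W - 1, scanMode = "half_turn_180")),
    "full_turn_360_offset")
})
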