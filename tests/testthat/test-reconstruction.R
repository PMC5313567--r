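test_that("FBP handles degenerate inputs and reconstructs a disk exactly", {
  g <- stdGeometry(nAngles = 360L, width = 128L)
  zero <- sinogram(matrix(0, 360, 128), angles(g), pixelSize = PX)
  expect_equal(values(fbp(zero)), matrix(0, 128, 128))
  # analytic disk: interior value within 2%, global RMSE within 5%
  r <- 1e-4; v <- 1e-7
  ell <- list(ellipseSpec(semiAxisA = r, semiAxisB = r, delta = v))
  g2 <- stdGeometry(nAngles = 720L, width = 256L)
  sg <- analyticSinogram(ell, g2, "delta")
  sl <- fbp(sg, "ramlak", quantity = "delta")
  ph <- makePhantom(ell, 256, PX)
  n <- 256; c0 <- (n - 1) / 2
  rr <- sqrt(outer(((0:(n - 1)) - c0)^2, ((0:(n - 1)) - c0)^2, `+`)) * PX
  expect_equal(mean(values(sl)[rr < 0.75 * r]), v, tolerance = 0.02)
  expect_lt(rmse(values(sl), ph@delta), 0.05 * v)
  # all filter windows run
  for (fl in c("shepp_logan", "hann"))
    expect_true(all(is.finite(values(fbp(sg, fl)))))
  # error paths
  bad <- values(sg); bad[5, 5] <- NaN
  expect_error(fbp(sinogram(bad, angles(g2), pixelSize = PX)), "non-finite")
  short <- sinogram(values(sg)[1:240, ], angles(g2)[1:240], pixelSize = PX)
  expect_error(fbp(short), "angle span")
  expect_error(fbp(sg, "nonsense"))
})

test_that("FBP is equivariant under joint sinogram/axis shifts", {
  ell <- list(ellipseSpec(centerX = 2e-5, semiAxisA = 8e-5, semiAxisB = 5e-5,
                          rotation = 40, delta = 1e-7))
  g <- stdGeometry(nAngles = 180L, width = 160L)
  sg <- analyticSinogram(ell, g, "delta")
  s <- 6L
  vs <- matrix(0, 180, 160)
  vs[, (1 + s):160] <- values(sg)[, 1:(160 - s)]
  sl1 <- fbp(sg)
  sl2 <- fbp(sinogram(vs, angles(g), pixelSize = PX),
             axisPosition = axisPosition(sg) + s)
  expect_equal(values(sl2), values(sl1), tolerance = 1e-6)
})

test_that("the forward projector matches the closed form and is linear", {
  ell <- list(ellipseSpec(semiAxisA = 2.4e-4, semiAxisB = 1.8e-4,
                          rotation = 25, delta = 1e-7))
  g <- stdGeometry(nAngles = 90L, width = 256L)
  ph <- makePhantom(ell, 256, PX)
  rf <- radonForward(ph@delta, angles(g), pixelSize = PX)
  ana <- values(analyticSinogram(ell, g, "delta"))
  expect_lt(relL2(values(rf), ana), 0.01)
  # linearity to machine precision
  set.seed(13)
  x <- matrix(rnorm(64 * 64), 64, 64); y <- matrix(rnorm(64 * 64), 64, 64)
  a <- 2.3; b <- -0.7
  rxy <- radonForward(a * x + b * y, c(0, 30, 77), pixelSize = PX)
  rx <- radonForward(x, c(0, 30, 77), pixelSize = PX)
  ry <- radonForward(y, c(0, 30, 77), pixelSize = PX)
  expect_equal(values(rxy), a * values(rx) + b * values(ry),
               tolerance = 1e-12)
  # a 180-degree rotation mirrors the detector coordinate
  r0 <- radonForward(x, 0, pixelSize = PX)
  r180 <- radonForward(x, 180, pixelSize = PX)
  expect_equal(values(r180)[1, ], rev(values(r0)[1, ]), tolerance = 1e-9)
})

test_that("SIRT converges on clean data and improves on FBP under noise", {
  g <- stdGeometry(nAngles = 60L, width = 128L, span = 180)
  ell <- list(ellipseSpec(semiAxisA = 1.1e-4, semiAxisB = 0.9e-4,
                          rotation = 10, delta = 1e-7, beta = 2e-9),
              ellipseSpec(centerX = 3e-5, centerY = 2e-5, semiAxisA = 3e-5,
                          semiAxisB = 2.2e-5, delta = 5e-8, beta = 1e-9))
  mu <- values(analyticSinogram(ell, g, "beta")) * 4 * pi / wavelength(g)
  # zero sinogram stays zero
  z <- sinogram(matrix(0, 60, 128), angles(g), pixelSize = PX)
  expect_equal(values(sirt(z, 5L)), matrix(0, 128, 128))
  # noise-free: data residual is non-increasing over 100 iterations
  sgC <- sinogram(mu, angles(g), pixelSize = PX)
  slC <- sirt(sgC, nIterations = 100L, nonneg = FALSE, supersample = 1L)
  res <- attr(slC, "residuals")
  expect_length(res, 100L)
  expect_true(all(diff(res) <= 1e-9 * res[1]))
  # Poisson-noisy low-angle scan: SIRT with nonneg beats FBP in RMSE
  set.seed(5)
  I0 <- 3000
  counts <- matrix(rpois(length(mu), I0 * exp(-mu)), nrow(mu))
  sgN <- sinogram(-log(pmax(counts, 1) / I0), angles(g), pixelSize = PX)
  muTrue <- makePhantom(ell, 128, PX)@beta * 4 * pi / wavelength(g)
  eF <- rmse(values(fbp(sgN, "shepp_logan", supersample = 1L)), muTrue)
  eS <- rmse(values(sirt(sgN, nIterations = 200L, nonneg = TRUE,
                         supersample = 1L)), muTrue)
  expect_lte(eS, eF)
  expect_error(sirt(sgN, nIterations = 0L), "nIterations")
})

test_that("FBP of the forward projection returns the phantom, and fewer
           angles reconstruct it strictly worse", {
  ell <- softPhantom()
  ph <- makePhantom(ell, 192, PX)
  full <- seq(0, 179.5, length.out = 360)
  rf <- radonForward(ph@delta, full, pixelSize = PX)
  sl <- fbp(rf, "shepp_logan", quantity = "delta")
  expect_gt(cor(as.vector(values(sl)), as.vector(ph@delta)), 0.99)
  expect_lt(rmse(values(sl), ph@delta) / diff(range(ph@delta)), 0.05)
  # halving the angles strictly increases the error
  half <- full[seq(1, 360, 2)]
  slH <- fbp(radonForward(ph@delta, half, pixelSize = PX), "shepp_logan",
             quantity = "delta")
  quarter <- full[seq(1, 360, 4)]
  slQ <- fbp(radonForward(ph@delta, quarter, pixelSize = PX), "shepp_logan",
             quantity = "delta")
  eF <- rmse(values(sl), ph@delta)
  eH <- rmse(values(slH), ph@delta)
  eQ <- rmse(values(slQ), ph@delta)
  expect_lt(eF, eH)
  expect_lt(eH, eQ)
})
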