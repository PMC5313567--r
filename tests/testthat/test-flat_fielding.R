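test_that("conventional flat fielding normalizes the canonical cases", {
  F_ <- matrix(1000 + 100 * sin(seq_len(64)), 8, 8)
  D_ <- matrix(40, 8, 8)
  expect_equal(conventionalFlatField(F_, F_, D_), matrix(1, 8, 8))
  expect_equal(conventionalFlatField(D_, F_, D_), matrix(0, 8, 8))
  expect_equal(conventionalFlatField(D_ + 0.5 * (F_ - D_), F_, D_),
               matrix(0.5, 8, 8))
  # clipping: output stays within [0, clipMax]
  out <- conventionalFlatField(F_ * 100, F_, D_, clipMax = 10)
  expect_true(all(out >= 0 & out <= 10))
  out2 <- conventionalFlatField(D_ - 500, F_, D_)
  expect_true(all(out2 >= 0))
  # flats darker than darks over >1% of pixels are refused
  expect_error(conventionalFlatField(F_, D_, F_), "bad flats")
  expect_error(conventionalFlatField(F_, F_[1:4, 1:4], D_), "shapes")
})

test_that("eigen flats: degenerate, rank-1 and low-rank drift cases", {
  darks <- array(10, c(2, 6, 9))
  # identical flats: empty basis
  b0 <- computeEigenFlats(array(500, c(5, 6, 9)), darks, 3L)
  expect_length(explainedVariance(b0), 0)
  expect_equal(dim(components(b0))[1], 0L)
  # two frames F +/- E: a single component proportional to E
  E <- matrix(rnorm(54), 6, 9)
  fl <- array(0, c(2, 6, 9))
  fl[1, , ] <- 600 + E; fl[2, , ] <- 600 - E
  b1 <- computeEigenFlats(fl, darks, 1L)
  expect_equal(explainedVariance(b1), 1)
  c1 <- components(b1)[1, , ]
  align <- sign(sum(c1 * E))
  expect_equal(align * c1, E / sqrt(sum(E^2)), tolerance = 1e-10)
  expect_error(computeEigenFlats(fl, darks, 2L), "smaller than")
  expect_error(computeEigenFlats(fl[1, , , drop = FALSE], darks, 1L),
               "at least two")
  # low-rank drift: the leading eigen images span the true components
  H <- 32L; W <- 128L
  nFB <- 40L; nFA <- 40L
  g <- stdGeometry(width = W)
  nT <- nFB + 180L + nFA
  drift <- makeDriftModel(H, W, nT, nComponents = 2L, amplitude = 0.06,
                          seed = 11L)
  cm <- corruptionModel(matrix(1, H, W), drift$images, drift$weights,
                        photonCount = 1e6, darkLevel = 20, seed = 7L)
  ell <- list(ellipseSpec(semiAxisA = 8e-5, semiAxisB = 6e-5, rotation = 30,
                          delta = 1e-7, beta = 2e-9))
  ps <- simulateParallelScan(ell, g, height = H, corruption = cm,
                             padding = 32L, nFlatsBefore = nFB,
                             nFlatsAfter = nFA, nDarks = 5L)
  basis <- computeEigenFlats(flats(ps, "all"), darks(ps), 4L)
  Vt <- qr.Q(qr(matrix(aperm(drift$images, c(2, 3, 1)), ncol = 2)))
  Ve <- matrix(aperm(components(basis)[1:2, , , drop = FALSE], c(2, 3, 1)),
               ncol = 2)
  pa <- acos(pmin(svd(crossprod(Vt, Ve))$d, 1)) * 180 / pi
  expect_true(all(pa < 5))
})

test_that("dynamic flat fielding recovers exact drift weights", {
  E <- matrix(rnorm(54), 6, 9); E <- E / sqrt(sum(E^2))
  F_ <- matrix(800, 6, 9); D_ <- matrix(25, 6, 9)
  basis <- new("EigenFlatBasis", meanFlat = F_, meanDark = D_,
               components = array(E, c(1, 6, 9)), explainedVariance = 1)
  # a projection that is exactly a drifted flat is normalized to 1
  P <- D_ + (F_ - D_) + 0.3 * E
  out <- dynamicFlatField(P, basis)
  expect_equal(attr(out, "weights"), 0.3, tolerance = 1e-10)
  expect_equal(matrix(out, 6, 9), matrix(1, 6, 9), tolerance = 1e-6)
  # empty basis falls back to the conventional formula bit-for-bit
  b0 <- new("EigenFlatBasis", meanFlat = F_, meanDark = D_,
            components = array(0, c(0, 6, 9)),
            explainedVariance = numeric(0))
  set.seed(8); P2 <- F_ + matrix(rnorm(54, sd = 5), 6, 9)
  expect_identical(dynamicFlatField(P2, b0),
                   conventionalFlatField(P2, F_, D_))
  # column-restricted estimation region works and is exact here too
  out3 <- dynamicFlatField(P, basis, estimationRegion = 1:4)
  expect_equal(attr(out3, "weights"), 0.3, tolerance = 1e-8)
  # a degenerate (empty) estimation region falls back with a warning
  expect_warning(out4 <- dynamicFlatField(P, basis,
                                          estimationRegion = integer(0)),
                 "falling back")
  expect_identical(matrix(out4, 6, 9),
                   matrix(conventionalFlatField(P, F_, D_), 6, 9))
})

test_that("with constant flats the dynamic stack equals the conventional one", {
  g <- stdGeometry(nAngles = 12L, width = 32L)
  set.seed(5)
  ps <- projectionSet(array(runif(12 * 4 * 32, 400, 900), c(12, 4, 32)),
                      flatsBefore = array(1000, c(4, 4, 32)),
                      darks = array(12, c(2, 4, 32)), geometry = g)
  conv <- flatFieldStack(ps, "conventional")
  dyn <- flatFieldStack(ps, "dynamic", nComponents = 2L)
  attr(dyn, "basis") <- NULL
  expect_identical(dyn, conv)
})

test_that("dynamic flat fielding halves the air-region scatter under drift", {
  d <- halfAcqDataset()
  air <- 1:40
  conv <- flatFieldStack(d$ps, "conventional")
  dyn <- flatFieldStack(d$ps, "dynamic", nComponents = 2L,
                        estimationRegion = air)
  cv <- function(s) sd(s[, , air]) / mean(s[, , air])
  expect_lt(cv(dyn), 0.5 * cv(conv))
  # correction never goes negative
  expect_true(all(dyn >= 0))
})
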