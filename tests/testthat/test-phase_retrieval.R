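test_that("Paganin retrieval has the exact contact limit and filter shape", {
  g0 <- stdGeometry(distance = 0, width = 64L)
  lam <- wavelength(g0)
  set.seed(11)
  t_ <- matrix(abs(rnorm(32 * 64, sd = 8e-5)), 32, 64)
  r <- 300; delta <- 1e-7; beta <- delta / r
  mu <- 4 * pi * beta / lam
  I0 <- exp(-mu * t_)
  cfg <- retrievalConfig("paganin", deltaBetaRatio = r, padding = 32L)
  out <- paganinRetrieve(I0, g0, cfg, delta = delta)
  # d = 0: exact Beer-Lambert inversion
  expect_equal(out$thickness, t_, tolerance = 1e-10)
  # unit intensity retrieves zero thickness at any distance
  g <- stdGeometry(width = 64L)
  out1 <- paganinRetrieve(matrix(1, 32, 64), g, cfg, delta = delta)
  expect_equal(out1$thickness, matrix(0, 32, 64), tolerance = 1e-12)
  # the filter is a monotone low-pass: H(0) = 1, strictly decreasing in |f|
  H <- pbitomo:::.paganinFilter(1, 257, g, 300)
  expect_equal(H[1, 1], 1)
  expect_true(all(diff(H[1, 1:129]) < 0))
  expect_error(paganinRetrieve(I0 - 2, g, cfg), "non-positive")
})

test_that("Paganin thickness is log-linear under flat intensity scaling", {
  g <- stdGeometry(width = 64L)
  lam <- wavelength(g)
  r <- 300; delta <- 1e-7; mu <- 4 * pi * (delta / r) / lam
  ell <- list(ellipseSpec(semiAxisA = 6e-5, semiAxisB = 6e-5,
                          delta = delta, beta = delta / r))
  gp <- geometry(40, PX, 2.2, c(0, 90), 64L)
  D <- matrix(values(analyticSinogram(ell, gp, "delta"))[1, ], 16, 64,
              byrow = TRUE)
  I <- propagate(D, D / r, g, padding = 32L)
  cfg <- retrievalConfig("paganin", deltaBetaRatio = r, padding = 32L)
  t1 <- paganinRetrieve(I, g, cfg, mu = mu)$thickness
  t2 <- paganinRetrieve(1.1 * I, g, cfg, mu = mu)$thickness
  expect_equal(t2, t1 - log(1.1) / mu, tolerance = 1e-6 * max(abs(t1)))
})

test_that("Paganin recovers projected thickness of a homogeneous sample", {
  W <- 256L; H <- 64L
  g <- geometry(40, PX, 2.2, seq(0, 179, 1), W)
  r <- 400; delta <- 1e-7
  ell <- list(ellipseSpec(semiAxisA = 2.2e-4, semiAxisB = 1.6e-4,
                          rotation = 15, delta = delta, beta = delta / r))
  tt <- values(analyticSinogram(ell, g, "thickness"))[40, ]
  D <- matrix(delta * tt, H, W, byrow = TRUE)
  I <- propagate(D, D / r, g, padding = 64L)
  cfg <- retrievalConfig("paganin", deltaBetaRatio = r, padding = 64L)
  rec <- paganinRetrieve(I, g, cfg, delta = delta)$thickness[H / 2, ]
  supp <- which(tt > 0)
  interior <- supp[4:(length(supp) - 3)]     # 3-px edge band excluded
  expect_lt(rmse(rec[interior], tt[interior]) /
              sqrt(mean(tt[interior]^2)), 0.05)
})

test_that("CTF retrieval is linear, finite at response zeros, and exact-ish
           in the weak pure-phase regime", {
  g <- stdGeometry(width = 256L)
  lam <- wavelength(g)
  phi <- dogPhase()
  I <- propagate(phi * lam / (2 * pi), 0 * phi, g)
  cfg <- retrievalConfig("ctf_pure_phase", regularization = 1e-6,
                         padding = 0L)
  rec <- ctfRetrieve(I, g, cfg)
  expect_lt(rmse(rec, phi - mean(phi)) / sqrt(mean((phi - mean(phi))^2)),
            0.02)
  # unit intensity retrieves zero phase
  expect_equal(ctfRetrieve(matrix(1, 64, 64), g, cfg), matrix(0, 64, 64))
  # exact linearity in the contrast
  C <- I - 1
  recHalf <- ctfRetrieve(1 + 0.5 * C, g, cfg)
  expect_equal(recHalf, 0.5 * rec, tolerance = 1e-8)
  # frequencies at sin(chi) = 0 stay finite thanks to the regularization
  set.seed(12)
  Iw <- 1 + 0.01 * matrix(rnorm(128 * 128), 128, 128)  # white spectrum
  recW <- ctfRetrieve(Iw, g, retrievalConfig("ctf_pure_phase",
                                             regularization = 1e-6,
                                             padding = 0L))
  expect_true(all(is.finite(recW)))
  expect_error(ctfRetrieve(I, stdGeometry(distance = 0, width = 256L), cfg),
               "positive propagation distance")
  expect_error(ctfRetrieve(I * 0, g, cfg), "strictly positive")
})

test_that("projected CTF clamps the response beyond the first maximum", {
  chi <- seq(0, 4, length.out = 200)
  Rp <- pbitomo:::.ctfResponse(chi, "projected_ctf", pi / 2)
  Rc <- pbitomo:::.ctfResponse(chi, "ctf_pure_phase", pi / 2)
  expect_equal(Rp[chi <= pi / 2], Rc[chi <= pi / 2])
  expect_true(all(Rp[chi > pi / 2] == Rp[which(chi > pi / 2)[1]]))
  # the clamped response never changes sign; the plain sine does
  expect_true(all(Rp <= 0))
  expect_true(any(Rc > 0))
})

test_that("TIE-Hom shows its low-pass cost against CTF on a sharp edge", {
  N <- 256L
  g <- stdGeometry(width = N)
  lam <- wavelength(g)
  x <- (0:(N - 1)) - (N - 1) / 2
  X <- matrix(x, N, N, byrow = TRUE); Y <- matrix(x, N, N)
  rr <- sqrt(X^2 + Y^2)
  phi <- 0.05 / (1 + exp((rr - 45) / 0.6))  # weak pure-phase disc
  I <- propagate(phi * lam / (2 * pi), 0 * phi, g, padding = 64L)
  r <- 1e5   # strong-smoothing ratio, as tuned for near-pure-phase samples
  pag <- paganinRetrieve(I, g, retrievalConfig("paganin",
                                               deltaBetaRatio = r,
                                               padding = 64L))
  pagPhi <- r / 2 * pag$pseudoAbsorption
  ctf <- ctfRetrieve(I, g, retrievalConfig("ctf_pure_phase",
                                           regularization = 1e-7,
                                           padding = 64L))
  rep_ <- compareRetrievals(pagPhi, ctf, phi, edgeRow = 128L,
                            edgeCols = 129:215)
  expect_gte(rep_$paganin$rise_distance_px, rep_$ctf$rise_distance_px)
  # tiny distance: both methods stay finite
  gt <- stdGeometry(distance = 1e-4, width = N)
  It <- propagate(phi * lam / (2 * pi), 0 * phi, gt, padding = 0L)
  p2 <- paganinRetrieve(It, gt, retrievalConfig("paganin",
                                                deltaBetaRatio = r,
                                                padding = 0L))
  c2 <- ctfRetrieve(It, gt, retrievalConfig("ctf_pure_phase",
                                            regularization = 1e-6,
                                            padding = 0L))
  r2 <- compareRetrievals(r / 2 * p2$pseudoAbsorption, c2, phi)
  expect_true(is.finite(r2$paganin$rmse) && is.finite(r2$ctf$rmse))
  # the report round-trips through YAML
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(rep_), f, precision = 15L)
  back <- yaml::read_yaml(f)
  expect_equal(back$paganin$rise_distance_px, rep_$paganin$rise_distance_px)
  expect_equal(back$ctf$rmse, rep_$ctf$rmse)
})
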