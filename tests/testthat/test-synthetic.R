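# Synthetic generators: Levy sampler, ballistic model, Gaussian-field
# oracle, telegraph modulation, frame-stack rendering, temperature scan.

test_that("symmetric Levy sampler has the right scaling limits", {
  set.seed(11)
  # mu = 2 reduces to a Gaussian with variance 2 scale^2
  x <- suppressWarnings(rLevySymmetric(2e5, 2, scale = 1.5))
  expect_equal(var(x), 2 * 1.5^2, tolerance = 0.03)
  expect_equal(mean(x), 0, tolerance = 0.02)
  # mu = 1 is Cauchy: empirical CF at k matches exp(-|scale k|)
  y <- suppressWarnings(rLevySymmetric(2e5, 1, scale = 2))
  expect_equal(mean(cos(0.3 * y)), exp(-2 * 0.3), tolerance = 0.01)
  # heavy-tail case stays finite thanks to the tail truncation
  z <- suppressWarnings(rLevySymmetric(2e5, 0.8))
  expect_true(all(is.finite(z)))
  expect_error(rLevySymmetric(10, 2.5), "\\(0, 2\\]")
  expect_error(rLevySymmetric(10, 0), "\\(0, 2\\]")
})

test_that("empirical Levy characteristic function gives the KWW field decay", {
  # E[exp(i q v t)] = exp(-(scale q t)^mu): the ballistic decorrelation law
  set.seed(12)
  for (mu in c(1.0, 1.5, 2.0)) {
    v <- suppressWarnings(rLevySymmetric(2e5, mu, scale = 0.25))
    for (qt in c(1, 2, 5))
      expect_equal(mean(cos(qt * v)), exp(-(0.25 * qt)^mu),
                   tolerance = 0.015)
  }
})

test_that("identical SimConfig and seed give bit-identical frame stacks", {
  cfg <- SimConfig(nFrames = 30, qTargets = c(0.08, 0.1), seed = 21,
                   meanCounts = 10)
  s1 <- renderFrameStack(cfg, testGeometry())
  s2 <- renderFrameStack(cfg, testGeometry())
  expect_identical(s1@frames, s2@frames)
  expect_identical(s1@timestamps, s2@timestamps)
  cfg2 <- cfg; cfg2@seed <- 22L
  s3 <- renderFrameStack(cfg2, testGeometry())
  expect_false(identical(s1@frames, s3@frames))
})

test_that("frozen scatterers give flat g2 at 1 + beta", {
  cfg <- SimConfig(velocityScale = 0, nFrames = 1500, nModes = 4,
                   nScatterers = 128, meanCounts = 200, frameInterval = 1,
                   qTargets = 0.1, seed = 31)
  sim <- simulateBallisticSeries(cfg, 0.1, nPixels = 600)
  cv <- computeG2(sim$counts, frameInterval = 1)
  # flat within noise and at the M-mode contrast level
  expect_lt(diff(range(g2Values(cv))), 0.01)
  expect_equal(mean(g2Values(cv)), 1.25, tolerance = 0.05)
})

test_that("Gaussian velocities (mu = 2) give a fitted exponent of 2", {
  # closed form: the stable CF at mu = 2 is exp(-(sigma q t)^2)
  sim <- quickBallistic(mu = 2, tau = 40, nFrames = 6000, nPixels = 80,
                        seed = 32)
  fit <- fitKWW(computeG2(sim$counts, frameInterval = 1))
  expect_equal(fit@alpha, 2, tolerance = 0.06)
  expect_equal(fit@tau, 40, tolerance = 0.05 * 40)
})

test_that("velocity redraw events slow the apparent decay", {
  # with Poisson redraws the accumulated displacement is subadditive, so
  # correlation at long lags sits above the event-free decay
  simEv <- quickBallistic(tau = 25, nFrames = 3000, nPixels = 60, seed = 33,
                          eventRate = 0.05)
  simNo <- quickBallistic(tau = 25, nFrames = 3000, nPixels = 60, seed = 33)
  lags <- c(40L, 60L, 80L)
  gEv <- g2Values(computeG2(simEv$counts, lags = lags))
  gNo <- g2Values(computeG2(simNo$counts, lags = lags))
  expect_true(all(gEv > gNo))
})

test_that("KWW oracle embedding is positive definite and exact", {
  for (a in c(0.8, 1.0, 1.5, 2.0)) {
    emb <- kwwEmbeddingSpectrum(50, a, 1000)
    expect_gte(emb$eigMin, -1e-10)
    # eigenvalues are the FFT of the wrapped covariance: check one directly
    k <- 0:(emb$m - 1)
    r <- exp(-(pmin(k, emb$m - k) / 50)^a)
    expect_equal(max(abs(emb$lambda - pmax(Re(fft(r)), 0))), 0,
                 tolerance = 1e-8)
  }
})

test_that("oracle series reproduce the analytic g2 at every lag", {
  # alpha = 1, tau = 50, beta = 1: g2(tau) - 1 = exp(-2) analytically
  sim <- kwwOracleSeries(tau = 50, alpha = 1, beta = 1, nFrames = 8000,
                         frameInterval = 1, nPixels = 60, seed = 41,
                         meanCounts = 100)
  cv <- computeG2(sim$counts, frameInterval = 1)
  target <- analyticG2(lagTimes(cv), 50, 1, 1)
  dev <- abs(g2Values(cv) - target) / g2Errors(cv)
  expect_lt(median(dev), 2)
  expect_lt(max(dev), 5)
  iTau <- which.min(abs(lagTimes(cv) - 50))
  expect_lt(abs(g2Values(cv)[iTau] - 1 - exp(-2)), 3 * g2Errors(cv)[iTau])
})

test_that("an infinite time constant freezes the oracle field", {
  sim <- kwwOracleSeries(tau = 1e9, alpha = 1.2, beta = 0.5,
                         nFrames = 500, nPixels = 400, seed = 42,
                         meanCounts = 200)
  cv <- computeG2(sim$counts, lags = c(1L, 5L, 20L, 100L, 200L))
  expect_equal(mean(g2Values(cv)), 1.5, tolerance = 0.08)
  expect_lt(diff(range(g2Values(cv))), 0.02)
})

test_that("ballistic generator and KWW oracle agree (anti-circularity)", {
  # matched (tau, alpha, beta): two independent generative paths must give
  # the same g2 within 3x pooled sampling error at every lag
  tau <- 40; mu <- 1.5
  simB <- quickBallistic(q = 0.1, tau = tau, mu = mu, nFrames = 6000,
                         nPixels = 100, seed = 51, nScatterers = 128)
  simO <- kwwOracleSeries(tau = tau, alpha = mu, beta = 0.25,
                          nFrames = 6000, nPixels = 100, seed = 52)
  cvB <- computeG2(simB$counts, frameInterval = 1)
  cvO <- computeG2(simO$counts, frameInterval = 1)
  pooled <- sqrt(g2Errors(cvB)^2 + g2Errors(cvO)^2)
  expect_true(all(abs(g2Values(cvB) - g2Values(cvO)) < 3 * pooled))
})

test_that("M-mode averaging sets the speckle contrast to 1/M", {
  for (M in c(1, 2, 8, 32)) {
    sim <- kwwOracleSeries(tau = 30, alpha = 1.5, beta = 1 / M,
                           nFrames = 3000, nPixels = 120, seed = 60 + M,
                           meanCounts = 100)
    est <- estimateContrast(sim$counts)
    expect_equal(est@beta, 1 / M, tolerance = 0.1)
  }
})

test_that("photon sampling at >= 50 counts leaves g2 within 1 sigma", {
  cfg <- SimConfig(velocityScale = velocityScaleFor(0.1, 40),
                   nFrames = 4000, meanCounts = 60, frameInterval = 1,
                   qTargets = 0.1, seed = 71)
  noisy <- simulateBallisticSeries(cfg, 0.1, nPixels = 80)
  clean <- noisy$intensity * cfg@meanCounts
  cvN <- computeG2(noisy$counts, frameInterval = 1)
  cvC <- computeG2(clean, frameInterval = 1)
  reldev <- abs(g2Values(cvN) - g2Values(cvC)) / g2Errors(cvN)
  expect_lt(median(reldev), 1)
  expect_lt(max(reldev), 3)
})

test_that("rendered stacks embed ground truth and reject bad targets", {
  cfg <- SimConfig(nFrames = 20, qTargets = c(0.08, 0.1), seed = 81,
                   meanCounts = 10)
  st <- renderFrameStack(cfg, testGeometry())
  gt <- st@metadata$groundTruth
  expect_equal(vapply(gt, `[[`, numeric(1), "q"), c(0.08, 0.1))
  expect_equal(gt[[1]]$beta, 0.25)
  # a q target beyond the detector names the valid interval
  cfgBad <- SimConfig(nFrames = 5, qTargets = 5, seed = 1)
  expect_error(renderFrameStack(cfgBad, testGeometry()), "valid detector Q")
})

test_that("telegraph modulation preserves the mean rate and amplitudes", {
  het <- HeterogeneitySchedule()
  expect_equal(telegraphOccupancy(het), 0.3, tolerance = 0.01)
  set.seed(91)
  sp <- telegraphSpeedFactor(het, 50000, 2, amplitude = 1)
  p <- telegraphOccupancy(het)
  k <- het@slowTau / het@fastTau
  gam <- 1 / (p * k + 1 - p)
  expect_setequal(round(unique(sp$speed), 6), round(c(k * gam, gam), 6))
  # mean-rate preservation holds exactly in expectation ...
  expect_equal(p * k * gam + (1 - p) * gam, 1, tolerance = 1e-12)
  # ... and approximately for one long realization
  expect_equal(mean(sp$speed), 1, tolerance = 0.2)
  # amplitude 0 switches modulation off
  sp0 <- telegraphSpeedFactor(het, 100, 2, amplitude = 0)
  expect_true(all(sp0$speed == 1))
  # amplitude profile is a Gaussian peaked at Tstar
  Ts <- seq(180, 290, by = 1)
  amp <- hetAmplitude(het, Ts)
  expect_equal(Ts[which.max(amp)], 227)
  expect_true(all(amp >= 0 & amp <= 1))
  expect_error(HeterogeneitySchedule(fastTau = 100, slowTau = 50),
               "smaller")
})

test_that("temperature scan ground truths follow Arrhenius plus coupling", {
  base <- SimConfig(nFrames = 12, qTargets = 0.1, seed = 101,
                    meanCounts = 5)
  # a = 0: observed tau equals the equilibrium tau0 at every temperature
  p0 <- TemperatureProtocol(temperatures = c(290, 250, 220, 180),
                            couplingA = 0)
  scan0 <- generateTemperatureScan(p0, base = base, het = NULL)
  for (st in scan0) {
    tr <- st@metadata$scanTruth
    expect_equal(tr$tauObs, tr$tau0, tolerance = 1e-12)
    expect_equal(tr$tau0, 1.8 * exp(9.4e3 / (8.314462618 * st@temperature)),
                 tolerance = 1e-9)
  }
  # with defaults, tau is monotone decreasing in T (increasing on cooling)
  p1 <- TemperatureProtocol()
  scan1 <- generateTemperatureScan(p1, base = base, het = NULL)
  taus <- vapply(scan1, function(s) s@metadata$scanTruth$tauObs, numeric(1))
  expect_true(all(diff(taus) > 0))  # grid runs 290 -> 180 K
  expect_lt(taus[1], taus[length(taus)])
})

test_that("simulation configs enforce their physical invariants", {
  expect_error(SimConfig(levyIndex = 2.5), "levyIndex")
  expect_error(SimConfig(nModes = 0), "nModes")
  expect_error(SimConfig(meanCounts = 0), "meanCounts")
  expect_error(SimConfig(qTargets = c(0.1, -0.2)), "positive")
  expect_error(TemperatureProtocol(temperatures = c(290, 250, 260)),
               "monotone")
})
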