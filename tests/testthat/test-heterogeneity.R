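# Dynamical heterogeneity: chi_T, chi_0(T), and the fast-timescale window
# analysis of the two-time correlation matrix.

# one shared telegraph realization at the study-like two-state conditions
.telegraphSim <- local({
  het <- HeterogeneitySchedule()   # 26 s / 220 s, fast occupancy 0.3
  cfg <- SimConfig(nFrames = 3000, frameInterval = 2, seed = 42,
                   qTargets = 0.1,
                   velocityScale = velocityScaleFor(0.1, telegraphBaseTau(het)))
  set.seed(1042)
  sp <- telegraphSpeedFactor(het, cfg@nFrames, cfg@frameInterval,
                             amplitude = 1)
  sim <- simulateBallisticSeries(cfg, 0.1, nPixels = 250,
                                 speedFactor = sp$speed)
  ttc <- computeTTC(sim$counts, frameInterval = 2, q = 0.1)
  beta <- estimateContrast(sim$counts)
  list(het = het, sim = sim, ttc = ttc, beta = beta,
       chi = computeChiT(ttc, beta, nBoot = 100))
})

test_that("chi_T of a noiseless homogeneous TTC is identically zero", {
  # analytic TTC built from the KWW correlation itself
  t <- 0:299
  g1 <- exp(-(abs(outer(t, t, `-`)) / 50)^1.5)
  C <- 1 + 0.25 * g1^2
  ttc <- TTCMatrix(q = 0.1, times = t, C = C, nPixels = 1000L)
  chi <- computeChiT(ttc, 0.25, nBoot = 20)
  expect_true(all(chiValues(chi) < 1e-20))
})

test_that("telegraph switching produces an interior chi_T maximum", {
  chi <- .telegraphSim$chi
  pk <- chiMax(chi)
  expect_false(pk$boundary)
  # the peak lag reflects the fast process: well below the slow constant
  expect_lt(pk$dtPeak, 120)
  expect_gt(pk$dtPeak, 5)
  # peak well above the homogeneous noise floor at long-and-short lags
  expect_gt(pk$chi0, 5 * min(chiValues(chi)))
})

test_that("telegraph chi_T agrees with a longer-run oracle estimate", {
  # brute-force reference: chi from an independent realization 3x longer,
  # same physics; curves must agree within their bootstrap errors
  het <- .telegraphSim$het
  cfg <- SimConfig(nFrames = 9000, frameInterval = 2, seed = 77,
                   qTargets = 0.1,
                   velocityScale = velocityScaleFor(0.1, telegraphBaseTau(het)))
  set.seed(1077)
  sp <- telegraphSpeedFactor(het, cfg@nFrames, cfg@frameInterval,
                             amplitude = 1)
  sim <- simulateBallisticSeries(cfg, 0.1, nPixels = 250,
                                 speedFactor = sp$speed)
  ttcL <- computeTTC(sim$counts, frameInterval = 2, q = 0.1,
                     maxFrames = 4500)
  chiL <- computeChiT(ttcL, .telegraphSim$beta, nBoot = 100)
  chiS <- .telegraphSim$chi
  common <- intersect(lagTimes(chiS), lagTimes(chiL))
  common <- common[common < 500]
  iS <- match(common, lagTimes(chiS)); iL <- match(common, lagTimes(chiL))
  pooled <- sqrt(chiS@se[iS]^2 + chiL@se[iL]^2)
  dev <- abs(chiValues(chiS)[iS] - chiValues(chiL)[iL]) / pooled
  expect_lt(median(dev), 2)
  expect_lt(max(dev), 5)
})

test_that("homogeneous chi_T shrinks towards its noise floor with size", {
  # stationary homogeneous process: median chi_T must decrease as pixels
  # and frames grow (three sizes)
  meds <- vapply(list(c(800, 40), c(1600, 80), c(3200, 160)),
                 function(sz) {
    sim <- kwwOracleSeries(tau = 30, alpha = 1.5, beta = 0.25,
                           nFrames = sz[1], nPixels = sz[2],
                           seed = 500 + sz[1])
    ttc <- computeTTC(sim$counts)
    chi <- computeChiT(ttc, 0.25, nBoot = 10,
                       dtGrid = c(5, 10, 20, 40, 80))
    median(chiValues(chi))
  }, numeric(1))
  expect_true(all(diff(meds) < 0))
})

test_that("chi_T is invariant under global intensity rescaling", {
  sim <- quickBallistic(tau = 30, nFrames = 1000, nPixels = 40, seed = 15)
  chi1 <- computeChiT(computeTTC(sim$counts), 0.25, nBoot = 5,
                      dtGrid = c(5, 20, 60))
  chi2 <- computeChiT(computeTTC(sim$counts * 11), 0.25, nBoot = 5,
                      dtGrid = c(5, 20, 60))
  expect_equal(chiValues(chi1), chiValues(chi2), tolerance = 1e-12)
})

test_that("chiMax handles ties and boundary maxima deterministically", {
  mk <- function(vals) new("ChiCurve", q = 0.1, dt = as.numeric(1:5),
                           chi = vals, se = rep(0.01, 5), nEff = rep(50L, 5),
                           normalization = "beta2", meta = list())
  tied <- chiMax(mk(c(0.1, 0.5, 0.5, 0.2, 0.1)))
  expect_equal(tied$dtPeak, 2)        # ties -> smaller lag
  mono <- chiMax(mk(c(0.5, 0.4, 0.3, 0.2, 0.1)))
  expect_true(mono$boundary)
  expect_error(chiMax(mk(rep(NA_real_, 5))), "no finite")
})

test_that("chi0 versus temperature flags flat series and short spans", {
  mk <- function(vals) new("ChiCurve", q = 0.1, dt = as.numeric(1:4),
                           chi = vals, se = rep(0.002, 4),
                           nEff = rep(50L, 4),
                           normalization = "beta2", meta = list())
  Tv <- c(290, 260, 240, 220, 200, 180)
  set.seed(3)
  flat <- lapply(Tv, function(x) mk(abs(rnorm(4, 0.01, 0.001))))
  s <- chi0VsTemperature(Tv, flat)
  expect_false(s@significant)
  peaked <- lapply(Tv, function(x)
    mk(rep(0.01 + 0.2 * exp(-(x - 225)^2 / 50), 4)))
  s2 <- chi0VsTemperature(Tv, peaked)
  expect_true(s2@significant)
  expect_equal(s2@Tpeak, 225, tolerance = 3)
  expect_error(chi0VsTemperature(290, flat[1]), "insufficient span")
})

test_that("fast timescale at the chi peak separates the two states", {
  ts <- timescaleAtChiPeak(.telegraphSim$ttc, .telegraphSim$chi,
                           .telegraphSim$beta)
  expect_gte(length(ts$tauWindows), 3)
  # windows recover the fast constant; global fit sits near the mixture
  expect_equal(ts$tauFast, 26, tolerance = 0.25 * 26)
  glob <- fitKWW(computeG2(.telegraphSim$sim$counts, frameInterval = 2))
  expect_gt(glob@tau, 3 * ts$tauFast)
  # the peak lag is far below the global relaxation time
  expect_lt(ts$dtPeak, glob@tau / 2)
})

test_that("homogeneous input gives window timescales equal to the global", {
  sim <- quickBallistic(q = 0.1, tau = 30, nFrames = 3000, nPixels = 250,
                        seed = 19, frameInterval = 1)
  ttc <- computeTTC(sim$counts, frameInterval = 1, q = 0.1)
  beta <- estimateContrast(sim$counts)
  chi <- computeChiT(ttc, beta, nBoot = 20)
  ts <- timescaleAtChiPeak(ttc, chi, beta)
  glob <- fitKWW(computeG2(sim$counts, frameInterval = 1))
  expect_equal(ts$tauFast, glob@tau, tolerance = 0.10 * glob@tau)
})
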