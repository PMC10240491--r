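# Model fits: KWW, dispersion, flux coupling, rescaling, Arrhenius, dip.

test_that("KWW fit is exact on noiseless model data", {
  t <- seq(2, 800, by = 2)
  y <- analyticG2(t, tau = 100, alpha = 1.5, beta = 0.3)
  fit <- fitKWW(G2Curve(q = 0.08, lags = t, g2 = y))
  expect_equal(fit@beta, 0.3, tolerance = 1e-6)
  expect_equal(fit@baseline, 1, tolerance = 1e-6)
  expect_equal(fit@tau, 100, tolerance = 1e-4)
  expect_equal(fit@alpha, 1.5, tolerance = 1e-6)
  # stretched case with a shifted baseline
  y2 <- analyticG2(t, tau = 60, alpha = 0.7, beta = 0.2, baseline = 1.01)
  fit2 <- fitKWW(G2Curve(q = 0.08, lags = t, g2 = y2))
  expect_equal(coef(fit2), c(beta = 0.2, baseline = 1.01, tau = 60,
                             alpha = 0.7), tolerance = 1e-4)
  expect_error(fitKWW(G2Curve(q = 0.1, lags = 1:4, g2 = rep(1, 4))),
               "6 lag")
})

test_that("unresolved decays are flagged at the tau bound", {
  t <- seq(1, 50)
  y <- analyticG2(t, tau = 500, alpha = 1, beta = 0.3)
  expect_warning(fitKWW(G2Curve(q = 0.1, lags = t, g2 = y),
                        bounds = list(tau = c(1, 100)),
                        fixed = list(baseline = 1)),
                 "unresolved decay")
})

test_that("KWW fits are unbiased in median with calibrated intervals", {
  # Monte Carlo over oracle replicates; spans long enough that the
  # finite-window estimator bias is inside the tolerance
  tau <- 25; alpha <- 1.5; nrep <- 120
  est <- matrix(NA_real_, nrep, 4)
  for (r in seq_len(nrep)) {
    sim <- kwwOracleSeries(tau = tau, alpha = alpha, beta = 0.25,
                           nFrames = 5000, nPixels = 50, seed = 3000 + r)
    f <- fitKWW(computeG2(sim$counts, frameInterval = 1))
    est[r, ] <- c(f@tau, f@se[["tau"]], f@alpha, f@se[["alpha"]])
  }
  expect_lt(abs(median(est[, 1]) - tau) / tau, 0.05)
  expect_lt(abs(median(est[, 3]) - alpha), 0.05)
  coverage <- mean(abs(est[, 1] - tau) < est[, 2])
  expect_gte(coverage, 0.6)
  expect_lte(coverage, 0.85)
})

test_that("flux-coupling fit is exact on noiseless inputs", {
  flux <- seq(0, 4.4e6, length.out = 6)
  tau <- 1 / (1 / 336 + 1.1e-8 * flux)
  fit <- fitFluxCoupling(flux, tau)
  expect_equal(fit@tau0, 336, tolerance = 1e-10)
  expect_equal(fit@a, 1.1e-8, tolerance = 1e-10)
  # a = 0: common tau recovered, coupling consistent with zero
  fit0 <- fitFluxCoupling(flux, rep(120, 6), se = rep(1, 6))
  expect_equal(fit0@tau0, 120, tolerance = 1e-8)
  expect_lt(fit0@a, 1e-12)
  expect_error(fitFluxCoupling(c(1e6, 1e6, 1e6), rep(50, 3)), "distinct")
  # rate extrapolates to a negative equilibrium rate -> explicit error
  f3 <- c(2e6, 3e6, 4e6)
  expect_error(fitFluxCoupling(f3, 1 / (1e-8 * f3 - 0.005)),
               "no finite equilibrium")
})

test_that("Arrhenius fit is exact, and flat series give Ea = 0", {
  Tv <- c(290, 260, 230, 200, 180)
  tau <- 1.8 * exp(9.4e3 / (8.314462618 * Tv))
  fit <- fitArrhenius(Tv, tau)
  expect_equal(fit@A, 1.8, tolerance = 1e-8)
  expect_equal(fit@Ea, 9.4, tolerance = 1e-8)
  flat <- fitArrhenius(Tv, rep(50, 5), se = rep(0.5, 5))
  expect_lt(abs(flat@Ea), 3 * flat@se[["Ea"]] + 1e-9)
  expect_error(fitArrhenius(Tv[1:3], tau[1:3]), "4 temperatures")
  expect_error(fitArrhenius(Tv, c(-1, tau[-1])), "non-positive")
})

test_that("Q-dispersion separates ballistic from diffusive dynamics", {
  q <- c(0.05, 0.08, 0.1, 0.15)
  mkFits <- function(rates, se = rates * 0.02) {
    lapply(seq_along(rates), function(i) {
      t <- seq(2, 2000, by = 2)
      cv <- G2Curve(q = q[i], lags = t,
                    g2 = analyticG2(t, 1 / rates[i], 1.5, 0.25),
                    se = rep(1e-4, length(t)))
      f <- fitKWW(cv)
      f@se[["tau"]] <- se[i] / rates[i]^2  # rate SE -> tau SE
      f
    })
  }
  # ballistic: rate = c q
  fB <- mkFits(0.2 * q)
  dB <- fitQDispersion(fB, q)
  expect_true(dB@isBallistic)
  expect_equal(dB@slope, 0.2, tolerance = 0.01)
  expect_lt(abs(dB@intercept), 2 * dB@se[["intercept"]])
  # diffusive: rate = D q^2 -> quadratic preferred by AIC
  fD <- mkFits(2 * q^2)
  dD <- fitQDispersion(fD, q)
  expect_false(dD@isBallistic)
  expect_lt(dD@aic[["quadratic"]], dD@aic[["linear"]])
  # all tau (nearly) equal -> slope consistent with zero
  set.seed(44)
  fE <- mkFits(0.02 * (1 + rnorm(4, 0, 5e-3)), se = rep(4e-4, 4))
  dE <- fitQDispersion(fE, q)
  expect_lt(abs(dE@slope), 2 * dE@se[["slope"]])
  expect_error(fitQDispersion(fB[1:2], q[1:2]), "3 Q bins")
})

test_that("time-axis rescaling collapses a synthetic flux family", {
  flux <- seq(0, 4.4e6, length.out = 5)
  tau0 <- 336; a <- 1.1e-8
  taus <- 1 / (1 / tau0 + a * flux)
  curves <- lapply(seq_along(flux), function(i) {
    t <- exp(seq(log(2), log(2500), length.out = 60))
    G2Curve(q = 0.08, lags = t,
            g2 = analyticG2(t, taus[i], 1.5, 0.25),
            se = rep(2e-4, length(t)),
            meta = list(fluxDensity = flux[i]))
  })
  kww <- lapply(curves, fitKWW)
  fit <- fitFluxCoupling(flux, vapply(kww, function(f) f@tau, numeric(1)))
  rs <- rescaleTimeAxis(curves, fit, kwwFits = kww)
  # F = 0 curve axis unchanged
  expect_equal(rs$curves[[1]]@lags, curves[[1]]@lags)
  expect_lt(rs$score, 0.02)
  # deliberately wrong coupling (x10) degrades the collapse by > 5x
  bad <- fit; bad@a <- fit@a * 10
  rsBad <- rescaleTimeAxis(curves, bad, kwwFits = kww)
  expect_gt(rsBad$score, 5 * rs$score)
})

test_that("collapse score is minimized at the true coupling parameters", {
  flux <- seq(0, 4.4e6, length.out = 5)
  tau0 <- 336; a <- 1.1e-8
  taus <- 1 / (1 / tau0 + a * flux)
  curves <- lapply(seq_along(flux), function(i) {
    t <- exp(seq(log(2), log(2500), length.out = 50))
    G2Curve(q = 0.08, lags = t, g2 = analyticG2(t, taus[i], 1.5, 0.25),
            meta = list(fluxDensity = flux[i]))
  })
  kww <- lapply(curves, fitKWW)
  scores <- matrix(NA_real_, 5, 5)
  fa <- seq(0.5, 1.5, length.out = 5)
  for (i in 1:5) for (j in 1:5) {
    pf <- new("FluxCouplingFit", tau0 = tau0 * fa[i], a = a * fa[j],
              se = c(tau0 = 1, a = 1e-9),
              perFlux = data.frame(flux = flux, tau = taus,
                                   se = NA_real_))
    scores[i, j] <- rescaleTimeAxis(curves, pf, kwwFits = kww)$score
  }
  expect_equal(which(scores == min(scores), arr.ind = TRUE)[1, ],
               c(row = 3L, col = 3L))
})

test_that("Gaussian-dip location is exact on model data and flags flats", {
  Tv <- c(290, 270, 250, 240, 230, 225, 220, 210, 195, 180)
  a <- 1.5 - 0.45 * exp(-(Tv - 227)^2 / (2 * 8^2))
  fit <- locateKWWMinimum(Tv, a, se = rep(0.02, 10))
  expect_equal(fit@Tmin, 227, tolerance = 1e-3)
  expect_equal(fit@depth, 0.45, tolerance = 1e-3)
  expect_true(fit@significant)
  # constant series: no significant dip
  set.seed(2)
  flat <- locateKWWMinimum(Tv, rep(1.5, 10) + rnorm(10, 0, 1e-3),
                           se = rep(0.02, 10))
  expect_false(flat@significant)
  expect_error(locateKWWMinimum(Tv[1:4], a[1:4]), "5 temperatures")
})
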