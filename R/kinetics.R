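# Model fits: KWW decays, Q dispersion, flux coupling, time-axis rescaling,
# Arrhenius temperature dependence, and the KWW-exponent minimum.

#' Fit a Kohlrausch-Williams-Watts decay to a g2 curve
#'
#' Weighted least squares of g2(t) = c + beta exp(-2 (t/tau)^alpha) with
#' weights 1/SE^2 (unweighted fallback when errors are absent). The factor 2
#' makes the underlying field correlation exp(-(t/tau)^alpha) (Siegert
#' relation), so the fitted tau matches the generators' field time constant.
#'
#' Default initial values: c = 1, beta = g2(first lag) - 1, tau = the lag
#' where (g2 - c)/beta is nearest exp(-2), alpha = 1.
#'
#' @param curve a \linkS4class{G2Curve}
#' @param bounds list with elements \code{alpha} (range) and \code{tau}
#'   (range, s); defaults alpha in (0.2, 3], tau in (frame interval,
#'   1e4 x lag span)
#' @param init optional named list/vector of starting values (beta,
#'   baseline, tau, alpha)
#' @param fixed optional named list of parameters to hold fixed (e.g.
#'   \code{list(baseline = 1, beta = 0.25)})
#' @return a \linkS4class{KWWFit}; non-convergence raises an error carrying
#'   the optimizer diagnostics, a time constant at its bound is flagged
#'   "unresolved decay" in the diagnostics
#' @examples
#' t <- seq(2, 600, by = 2)
#' g2 <- 1 + 0.3 * exp(-2 * (t / 100)^1.5)
#' fit <- fitKWW(G2Curve(q = 0.1, lags = t, g2 = g2))
#' coef(fit)
#' @export
fitKWW <- function(curve, bounds = NULL, init = NULL, fixed = list()) {
  stopifnot(is(curve, "G2Curve"))
  t <- curve@lags
  y <- curve@g2
  if (length(t) < 6L) stop("need at least 6 lag points spanning the decay")
  span <- max(t) - min(t)
  dt <- if (is.finite(curve@frameInterval)) curve@frameInterval else min(t)
  b <- list(alpha = c(0.2, 3), tau = c(dt, 1e4 * span))
  if (!is.null(bounds)) b <- modifyList(b, bounds)
  w <- 1 / curve@se^2
  weighted <- all(is.finite(w))
  if (!weighted) w <- rep(1, length(t))
  c0 <- 1
  beta0 <- max(y[1L] - c0, 1e-3)
  target <- c0 + beta0 * exp(-2)
  tau0 <- t[which.min(abs(y - target))]
  tau0 <- min(max(tau0, b$tau[1L] * 1.01), b$tau[2L] * 0.99)
  start <- list(beta = beta0, baseline = c0, tau = tau0, alpha = 1)
  if (!is.null(init)) start <- modifyList(start, as.list(init))
  start[names(fixed)] <- NULL
  lower <- c(beta = 1e-6, baseline = -Inf, tau = b$tau[1L],
             alpha = b$alpha[1L])[names(start)]
  upper <- c(beta = 2, baseline = Inf, tau = b$tau[2L],
             alpha = b$alpha[2L])[names(start)]
  dat <- c(list(t = t, y = y, w = w), fixed)
  form <- y ~ baseline + beta * exp(-2 * (t / tau)^alpha)
  fit <- tryCatch(
    minpack.lm::nlsLM(form, start = start, lower = lower, upper = upper,
                      weights = w, data = dat,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop("KWW fit did not converge: ", conditionMessage(e),
           " (n = ", length(t), ", init tau = ", signif(tau0, 3), " s)",
           call. = FALSE))
  cf <- coef(fit)
  full <- c(as.list(cf), fixed)
  covFit <- matrix(NA_real_, length(cf), length(cf),
                   dimnames = list(names(cf), names(cf)))
  seFit <- setNames(rep(NA_real_, 4),
                    c("beta", "baseline", "tau", "alpha"))
  cv <- tryCatch(vcov(fit), error = function(e) NULL)
  if (!is.null(cv) && all(is.finite(cv))) {
    covFit <- cv
    seFit[colnames(cv)] <- sqrt(pmax(diag(cv), 0))
  }
  seFit[names(fixed)] <- 0
  seMethod <- "nls-vcov"
  # leave-one-pixel-out refits: pixels are independent, so the jackknife
  # over pixels gives calibrated parameter errors even though residuals
  # are correlated across lags (where the plain nls vcov under-covers)
  loo <- curve@meta$looG2
  if (is.matrix(loo) && ncol(loo) >= 10L && nrow(loo) == length(y)) {
    np <- ncol(loo)
    cfs <- matrix(NA_real_, np, length(cf),
                  dimnames = list(NULL, names(cf)))
    for (p in seq_len(np)) {
      datP <- dat
      datP$y <- loo[, p]
      fp <- tryCatch(
        minpack.lm::nlsLM(form, start = as.list(cf), lower = lower,
                          upper = upper, weights = w, data = datP,
                          control = minpack.lm::nls.lm.control(
                            maxiter = 100)),
        error = function(e) NULL)
      if (!is.null(fp)) cfs[p, ] <- coef(fp)
    }
    ok <- complete.cases(cfs)
    if (sum(ok) >= 0.8 * np) {
      cfs <- cfs[ok, , drop = FALSE]
      nOk <- nrow(cfs)
      dev <- sweep(cfs, 2L, colMeans(cfs))
      covJK <- (nOk - 1L) / nOk * crossprod(dev)
      covFit <- covJK
      seFit[colnames(cfs)] <- sqrt(pmax(diag(covJK), 0))
      seFit[names(fixed)] <- 0
      seMethod <- "pixel-jackknife"
    }
  }
  atBound <- full$tau <= b$tau[1L] * 1.02 || full$tau >= b$tau[2L] * 0.98
  if (atBound)
    warning("unresolved decay: fitted tau at its bound (",
            signif(full$tau, 3), " s)")
  res <- y - predict(fit)
  new("KWWFit", beta = full$beta, baseline = full$baseline, tau = full$tau,
      alpha = full$alpha, se = seFit, cov = covFit,
      diagnostics = list(residualNorm = sqrt(sum(w * res^2)),
                         nPoints = length(t), weighted = weighted,
                         tauAtBound = atBound, seMethod = seMethod,
                         convInfo = fit$convInfo))
}

#' Fit the linear Q dispersion of the decay rate
#'
#' Weighted linear regression of 1/tau on Q across per-bin KWW fits. A
#' ballistic (directed) process has rate proportional to Q; the fit reports
#' an \code{isBallistic} flag (intercept consistent with 0 at 2 SE) and the
#' AIC of linear-in-Q versus quadratic-in-Q through-origin rate models
#' (diffusive dynamics prefer the quadratic).
#'
#' @param fits list of \linkS4class{KWWFit}, one per Q bin
#' @param q momentum transfers (1/nm) matching \code{fits}
#' @return a \linkS4class{DispersionFit}
#' @export
fitQDispersion <- function(fits, q) {
  if (length(fits) < 3L) stop("need at least 3 Q bins with valid fits")
  stopifnot(length(q) == length(fits))
  tau <- vapply(fits, function(f) f@tau, numeric(1))
  tauSE <- vapply(fits, function(f) f@se[["tau"]], numeric(1))
  rate <- 1 / tau
  rateSE <- tauSE / tau^2
  w <- if (all(is.finite(rateSE)) && all(rateSE > 0)) 1 / rateSE^2
       else rep(1, length(rate))
  fit <- lm(rate ~ q, weights = w)
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  aicLin <- AIC(lm(rate ~ 0 + q, weights = w))
  aicQuad <- AIC(lm(rate ~ 0 + I(q^2), weights = w))
  new("DispersionFit", slope = unname(cf[2L]), intercept = unname(cf[1L]),
      se = c(slope = unname(se[2L]), intercept = unname(se[1L])),
      rates = data.frame(q = q, rate = rate, se = rateSE),
      isBallistic = abs(cf[1L]) < 2 * se[1L] && aicLin <= aicQuad,
      aic = c(linear = aicLin, quadratic = aicQuad))
}

#' Fit the beam-flux coupling model 1/tau = 1/tau0 + a F
#'
#' Weighted linear regression of the decay rate on flux density, with
#' errors propagated from the tau standard errors; tau0 = 1/intercept and
#' a = slope, with SEs by the delta method.
#'
#' @param flux flux densities ((ph/s)/um^2), at least 3 distinct values
#' @param tau fitted time constants (s)
#' @param se standard errors of tau (optional)
#' @return a \linkS4class{FluxCouplingFit}; a non-positive intercept raises
#'   "no finite equilibrium time constant resolvable"
#' @export
fitFluxCoupling <- function(flux, tau, se = NULL) {
  if (length(unique(flux)) < 3L)
    stop("need at least 3 distinct flux densities")
  stopifnot(length(tau) == length(flux), all(tau > 0))
  rate <- 1 / tau
  if (is.null(se)) se <- rep(NA_real_, length(tau))
  rateSE <- se / tau^2
  w <- if (all(is.finite(rateSE)) && all(rateSE > 0)) 1 / rateSE^2
       else rep(1, length(rate))
  fit <- lm(rate ~ flux, weights = w)
  cf <- coef(fit)
  seFit <- sqrt(diag(vcov(fit)))
  if (cf[1L] <= 0)
    stop("no finite equilibrium time constant resolvable ",
         "(rate intercept ", signif(cf[1L], 3), " <= 0)")
  new("FluxCouplingFit", tau0 = unname(1 / cf[1L]),
      a = unname(max(cf[2L], 0)),
      se = c(tau0 = unname(seFit[1L] / cf[1L]^2), a = unname(seFit[2L])),
      perFlux = data.frame(flux = flux, tau = tau, se = se))
}

#' Rescale g2 time axes by the beam-coupling factor
#'
#' Expresses each curve's lag axis in units of its flux-dependent decay by
#' applying the factor (1 + a F tau0) = tau0/tau(F), the factor by which
#' the beam accelerates the decay at flux density F; after rescaling,
#' curves from different flux densities collapse onto the equilibrium
#' decay and the F = 0 axis is unchanged. The
#' collapse score is the maximum over a common rescaled-lag grid of the
#' spread of the normalized decays (g2 - c)/beta across curves; the pooled
#' interpolated standard error is returned for comparison.
#'
#' @param curves list of \linkS4class{G2Curve}; each must carry its flux
#'   density in \code{meta$fluxDensity}
#' @param fit a \linkS4class{FluxCouplingFit}
#' @param kwwFits optional list of per-curve \linkS4class{KWWFit} supplying
#'   (beta, c); fitted internally when absent
#' @param nGrid points of the common evaluation grid
#' @return list: \code{curves} (rescaled), \code{score} (max spread),
#'   \code{pooledSE}, \code{grid}
#' @export
rescaleTimeAxis <- function(curves, fit, kwwFits = NULL, nGrid = 40) {
  stopifnot(is(fit, "FluxCouplingFit"))
  if (is.null(kwwFits)) kwwFits <- lapply(curves, fitKWW)
  flux <- vapply(curves, function(cv) {
    f <- cv@meta$fluxDensity
    if (is.null(f) || !is.finite(f))
      stop("each curve needs meta$fluxDensity")
    f
  }, numeric(1))
  factors <- 1 + fit@a * flux * fit@tau0
  rescaled <- mapply(function(cv, fac) {
    cv@lags <- cv@lags * fac
    cv@meta$rescaleFactor <- fac
    cv
  }, curves, factors, SIMPLIFY = FALSE)
  lo <- max(vapply(rescaled, function(cv) min(cv@lags), numeric(1)))
  hi <- min(vapply(rescaled, function(cv) max(cv@lags), numeric(1)))
  grid <- exp(seq(log(lo), log(hi), length.out = nGrid))
  ynorm <- mapply(function(cv, kf) {
    approx(cv@lags, (cv@g2 - kf@baseline) / kf@beta, xout = grid,
           rule = 2)$y
  }, rescaled, kwwFits)
  enorm <- mapply(function(cv, kf) {
    if (all(is.na(cv@se))) return(rep(NA_real_, length(grid)))
    approx(cv@lags, cv@se / kf@beta, xout = grid, rule = 2)$y
  }, rescaled, kwwFits)
  spread <- apply(ynorm, 1L, function(r) diff(range(r)))
  # pooled across the family: the spread of n curves is compared against
  # the quadrature sum of their interpolated errors
  pooledSE <- if (all(is.na(enorm))) NA_real_ else
    mean(sqrt(rowSums(enorm^2)), na.rm = TRUE)
  list(curves = rescaled, score = max(spread), pooledSE = pooledSE,
       grid = grid, spread = spread)
}

#' Fit the Arrhenius law tau(T) = A exp(Ea / (R T))
#'
#' Weighted linear regression of ln(tau) on 1/T; Ea = slope * R (kJ/mol),
#' A = exp(intercept) (s), with propagated standard errors. Time constants
#' grow on cooling for positive Ea.
#'
#' @param temperature temperatures (K), at least 4
#' @param tau time constants (s), all positive
#' @param se standard errors of tau (optional)
#' @return an \linkS4class{ArrheniusFit}
#' @export
fitArrhenius <- function(temperature, tau, se = NULL) {
  if (length(temperature) < 4L) stop("need at least 4 temperatures")
  stopifnot(length(tau) == length(temperature))
  if (any(!is.finite(tau) | tau <= 0))
    stop("non-positive time constants rejected")
  if (is.null(se)) se <- rep(NA_real_, length(tau))
  lnTau <- log(tau)
  lnSE <- se / tau
  w <- if (all(is.finite(lnSE)) && all(lnSE > 0)) 1 / lnSE^2
       else rep(1, length(tau))
  x <- 1 / temperature
  fit <- lm(lnTau ~ x, weights = w)
  cf <- coef(fit)
  seFit <- sqrt(diag(vcov(fit)))
  A <- exp(unname(cf[1L]))
  new("ArrheniusFit", A = A, Ea = unname(cf[2L]) * .RGAS / 1000,
      se = c(A = A * unname(seFit[1L]),
             Ea = unname(seFit[2L]) * .RGAS / 1000),
      fitData = data.frame(temperature = temperature, tau = tau, se = se))
}

#' Locate the KWW-exponent minimum versus temperature
#'
#' Fits the Gaussian-dip model
#' alpha(T) = baseline - depth exp(-(T - Tmin)^2 / (2 width^2)) by weighted
#' least squares. When the fit does not converge the discrete argmin is
#' reported instead (ties resolved towards lower temperature) with the dip
#' flagged not significant. Significance requires depth > 2 SE(depth).
#'
#' @param temperature temperatures (K), at least 5 spanning the candidate
#'   minimum
#' @param alpha KWW exponents
#' @param se standard errors of alpha (optional)
#' @return a \linkS4class{MinimumFit}
#' @export
locateKWWMinimum <- function(temperature, alpha, se = NULL) {
  if (length(temperature) < 5L) stop("need at least 5 temperatures")
  stopifnot(length(alpha) == length(temperature))
  if (is.null(se)) se <- rep(NA_real_, length(alpha))
  w <- if (all(is.finite(se)) && all(se > 0)) 1 / se^2
       else rep(1, length(alpha))
  ord <- order(temperature)
  Tv <- temperature[ord]; av <- alpha[ord]; wv <- w[ord]
  # argmin with ties towards lower temperature
  iMin <- which(av == min(av))[1L]
  base0 <- median(av[-iMin])
  start <- list(baseline = base0, depth = max(base0 - av[iMin], 1e-3),
                Tmin = Tv[iMin], width = diff(range(Tv)) / 10)
  dat <- list(Tv = Tv, av = av, wv = wv)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      av ~ baseline - depth * exp(-(Tv - Tmin)^2 / (2 * width^2)),
      start = start, weights = wv, data = dat,
      lower = c(baseline = 0, depth = 0, Tmin = min(Tv),
                width = diff(range(Tv)) / 50),
      upper = c(baseline = 3, depth = 3, Tmin = max(Tv),
                width = diff(range(Tv))),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(new("MinimumFit", Tmin = Tv[iMin], depth = base0 - av[iMin],
               width = NA_real_, baseline = base0,
               se = c(Tmin = NA_real_, depth = NA_real_, width = NA_real_,
                      baseline = NA_real_),
               significant = FALSE, method = "argmin"))
  }
  cf <- coef(fit)
  seFit <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
    setNames(rep(NA_real_, 4), names(cf)))
  sig <- is.finite(seFit[["depth"]]) && cf[["depth"]] > 2 * seFit[["depth"]]
  new("MinimumFit", Tmin = cf[["Tmin"]], depth = cf[["depth"]],
      width = cf[["width"]], baseline = cf[["baseline"]],
      se = c(Tmin = seFit[["Tmin"]], depth = seFit[["depth"]],
             width = seFit[["width"]], baseline = seFit[["baseline"]]),
      significant = sig, method = "gaussian")
}
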