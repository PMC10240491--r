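# Synthetic speckle generators.
#
# Two independent generative paths validate each other:
#  * a physical scatterer-sum model (Levy-stable ballistic velocities,
#    Poisson-timed redraw events, M coherence modes, Poisson photons), and
#  * a statistical Gaussian-field oracle (circulant spectral embedding of
#    the KWW field covariance) whose expected g2 is known exactly.

# ------------------------------------------------------------- Levy draws --

#' Symmetric Levy-stable random velocities
#'
#' Chambers-Mallows-Stuck sampler for the symmetric alpha-stable law with
#' characteristic function exp(-|scale * k|^mu). Draws beyond the ~1-1e-6
#' tail quantile (computed from the asymptotic Pareto tail) are resampled
#' with a warning: a controlled truncation that prevents position overflow
#' for extreme draws at small mu.
#'
#' @param n number of draws
#' @param mu stability index in (0, 2]
#' @param scale stable scale parameter
#' @return numeric vector of draws
#' @export
rLevySymmetric <- function(n, mu, scale = 1) {
  if (mu <= 0 || mu > 2) stop("Levy index mu must lie in (0, 2]")
  if (n == 0L) return(numeric(0))
  draw <- function(m) {
    th <- runif(m, -pi / 2, pi / 2)
    w <- rexp(m)
    if (abs(mu - 1) < 1e-10) {
      tan(th)
    } else if (mu == 2) {
      2 * sin(th) * sqrt(w)
    } else {
      (sin(mu * th) / cos(th)^(1 / mu)) *
        (cos((1 - mu) * th) / w)^((1 - mu) / mu)
    }
  }
  cap <- .levyTailQuantile(mu, 1e-6)
  x <- draw(n)
  for (it in 1:100) {
    bad <- which(!is.finite(x) | abs(x) > cap)
    if (!length(bad)) break
    if (it == 1L)
      warning(length(bad), " extreme Levy draw(s) resampled ",
              "(truncation at the ~1-1e-6 tail quantile)")
    x[bad] <- draw(length(bad))
  }
  x[!is.finite(x) | abs(x) > cap] <- cap  # last resort, essentially unreachable
  scale * x
}

# Approximate two-sided tail quantile |X| of the standard symmetric stable
# law from P(|X| > x) ~ 2 C_mu x^-mu, C_mu = sin(pi mu / 2) Gamma(mu) / pi.
.levyTailQuantile <- function(mu, p) {
  if (mu == 2) return(qnorm(1 - p / 2, sd = sqrt(2)))
  cmu <- sin(pi * mu / 2) * gamma(mu) / pi
  (2 * cmu / p)^(1 / mu)
}

# --------------------------------------------------------------- telegraph --

#' Simulate a two-state telegraph speed-factor series
#'
#' Draws a stationary telegraph realization between a fast and a slow
#' dynamical state and converts it into a per-frame speed factor for the
#' ballistic generator. The two factors are mean-rate preserving:
#' m_fast = k gamma, m_slow = gamma with gamma = 1/(p k + 1 - p), where p is
#' the stationary fast-state occupancy and the rate contrast
#' k = 1 + amplitude (slowTau/fastTau - 1). At amplitude 1 and base time
#' constant \code{telegraphBaseTau(schedule)} the two states decay exactly
#' with fastTau and slowTau.
#'
#' @param schedule a \linkS4class{HeterogeneitySchedule}
#' @param nFrames frames
#' @param frameInterval frame spacing (s)
#' @param amplitude intermittency strength in [0, 1]
#' @return list with \code{speed} (length nFrames) and \code{state}
#'   (1 = fast, 2 = slow)
#' @export
telegraphSpeedFactor <- function(schedule, nFrames, frameInterval,
                                 amplitude = 1) {
  rates <- schedule@stateRates        # c(fast->slow, slow->fast)
  p <- rates[2L] / sum(rates)         # stationary fast occupancy
  k <- 1 + amplitude * (schedule@slowTau / schedule@fastTau - 1)
  gam <- 1 / (p * k + (1 - p))
  span <- nFrames * frameInterval
  state <- integer(0)
  s <- if (runif(1) < p) 1L else 2L
  t0 <- 0
  stateAt <- rep(NA_integer_, nFrames)
  tGrid <- (seq_len(nFrames) - 1) * frameInterval
  while (t0 <= span) {
    dwell <- rexp(1, rates[s])
    stateAt[tGrid >= t0 & tGrid < t0 + dwell] <- s
    t0 <- t0 + dwell
    s <- 3L - s
  }
  speed <- ifelse(stateAt == 1L, k * gam, gam)
  list(speed = speed, state = stateAt)
}

#' Stationary fast-state occupancy of a schedule
#' @param schedule a \linkS4class{HeterogeneitySchedule}
#' @return occupancy in (0, 1)
#' @export
telegraphOccupancy <- function(schedule)
  schedule@stateRates[2L] / sum(schedule@stateRates)

#' Base time constant making telegraph states hit fastTau and slowTau
#'
#' With the mean-rate-preserving factors of
#' \code{\link{telegraphSpeedFactor}} at amplitude 1, a generator whose
#' homogeneous time constant equals this value decays exactly with
#' \code{fastTau} in the fast state and \code{slowTau} in the slow state.
#'
#' @param schedule a \linkS4class{HeterogeneitySchedule}
#' @return time constant (s)
#' @export
telegraphBaseTau <- function(schedule) {
  p <- telegraphOccupancy(schedule)
  1 / (p / schedule@fastTau + (1 - p) / schedule@slowTau)
}

# -------------------------------------------------------- ballistic model --

#' Simulate ballistic-scatterer speckle intensity series
#'
#' Each pixel is an independent speckle realization: a coherent sum
#' E(t) = sum_j exp(i q x_j(t)) over point scatterers whose velocities are
#' drawn from a symmetric Levy-stable law of index mu and redrawn at
#' Poisson-timed stress-release events. Between events the field correlation
#' is exp(-(velocityScale * q * t)^mu), so the KWW exponent recovered by the
#' analysis pipeline equals mu and the decay rate is linear in q. The
#' intensity is averaged over \code{nModes} independent mode realizations
#' (speckle contrast 1/nModes) and Poisson-sampled at \code{meanCounts}.
#'
#' @param cfg a \linkS4class{SimConfig}
#' @param q momentum transfer (1/nm)
#' @param nPixels independent pixel realizations
#' @param speedFactor optional per-frame speed modulation (length nFrames),
#'   e.g. from \code{\link{telegraphSpeedFactor}}; the instantaneous decay
#'   rate is multiplied by it
#' @param seed RNG seed; default \code{cfg@seed}, NA to leave the RNG state
#'   untouched (for callers that manage seeding)
#' @param photonNoise Poisson-sample the intensities (TRUE) or return the
#'   noiseless intensities scaled to meanCounts (FALSE)
#' @return list: \code{counts} (nFrames x nPixels matrix), \code{intensity}
#'   (noiseless, unit mean), \code{truth} (tau, alpha, beta at this q)
#' @examples
#' cfg <- SimConfig(nFrames = 500, velocityScale = velocityScaleFor(0.1, 50))
#' sim <- simulateBallisticSeries(cfg, q = 0.1, nPixels = 20)
#' @export
simulateBallisticSeries <- function(cfg, q, nPixels = 100,
                                    speedFactor = NULL, seed = cfg@seed,
                                    photonNoise = TRUE) {
  stopifnot(is(cfg, "SimConfig"), q > 0, nPixels >= 1)
  if (!is.na(seed)) set.seed(seed)
  nf <- cfg@nFrames
  ns <- cfg@nScatterers
  nreal <- nPixels * cfg@nModes
  if (is.null(speedFactor)) speedFactor <- rep(1, nf)
  if (length(speedFactor) != nf)
    stop("speedFactor must have one entry per frame")
  # per-frame phase step at unit velocity; time is carried in frame units
  qdt <- q * cfg@frameInterval
  phi0 <- matrix(runif(ns * nreal, 0, 2 * pi), ns, nreal)
  v0 <- matrix(rLevySymmetric(ns * nreal, cfg@levyIndex, cfg@velocityScale),
               ns, nreal)
  evFrame <- integer(0); evReal <- integer(0); evScat <- integer(0)
  evVel <- numeric(0)
  if (cfg@eventRate > 0) {
    pEvent <- 1 - exp(-cfg@eventRate * cfg@frameInterval)
    for (r in seq_len(nreal)) {
      nEv <- rbinom(ns, nf - 1L, pEvent)
      tot <- sum(nEv)
      if (tot == 0L) next
      scat <- rep(seq_len(ns), nEv)
      frames <- unlist(lapply(nEv[nEv > 0L], function(k)
        sort(sample.int(nf - 1L, k, replace = FALSE))), use.names = FALSE)
      o <- order(scat * 0L + frames)  # events applied in frame order
      evFrame <- c(evFrame, frames[o])
      evScat <- c(evScat, scat[o])
      evReal <- c(evReal, rep(r, tot))
      evVel <- c(evVel, rLevySymmetric(tot, cfg@levyIndex,
                                       cfg@velocityScale))
    }
  }
  intensity <- speckleFieldIntensity(v0, phi0, qdt, speedFactor,
                                     as.integer(evFrame), # 1-based frames map
                                     as.integer(evReal) - 1L,
                                     as.integer(evScat) - 1L, evVel)
  # average over modes -> contrast 1/nModes
  if (cfg@nModes > 1L) {
    idx <- rep(seq_len(nPixels), each = cfg@nModes)
    intensity <- t(rowsum(t(intensity), idx)) / cfg@nModes
  }
  counts <- if (photonNoise) {
    matrix(rpois(length(intensity), cfg@meanCounts * intensity),
           nf, nPixels)
  } else {
    cfg@meanCounts * intensity
  }
  truth <- list(
    tau = if (cfg@velocityScale > 0) 1 / (cfg@velocityScale * q) else Inf,
    alpha = cfg@levyIndex, beta = 1 / cfg@nModes, q = q,
    eventRate = cfg@eventRate)
  list(counts = counts, intensity = intensity, truth = truth)
}

# ------------------------------------------------------------- KWW oracle --

#' Gaussian-field oracle with exact KWW correlation
#'
#' Draws stationary circularly symmetric complex Gaussian processes whose
#' autocorrelation is exactly exp(-(t/tau)^alpha), using circulant spectral
#' embedding (exp(-|t|^alpha) is a stable characteristic function, hence
#' positive definite for alpha <= 2). The intensity is the average of
#' M = round(1/beta) squared-magnitude realizations, so the expected
#' correlation is g2(t) = 1 + beta exp(-2 (t/tau)^alpha) exactly,
#' independent of any scatterer model.
#'
#' @param tau field time constant (s)
#' @param alpha KWW exponent in (0, 2]
#' @param beta target speckle contrast in (0, 1]
#' @param nFrames frames
#' @param frameInterval frame spacing (s)
#' @param nPixels independent pixel realizations
#' @param meanCounts mean photons/pixel/frame (for Poisson sampling)
#' @param seed RNG seed (NA: leave RNG state untouched)
#' @param photonNoise Poisson-sample (TRUE) or return scaled intensities
#' @return list: \code{counts}, \code{intensity}, \code{truth},
#'   \code{eigMin} (smallest embedding eigenvalue before clipping, relative
#'   to the largest)
#' @export
kwwOracleSeries <- function(tau, alpha, beta = 0.25, nFrames = 2000,
                            frameInterval = 1, nPixels = 100,
                            meanCounts = 60, seed = NA, photonNoise = TRUE) {
  stopifnot(alpha > 0, alpha <= 2, tau > 0, beta > 0, beta <= 1)
  if (!is.na(seed)) set.seed(seed)
  M <- max(1L, as.integer(round(1 / beta)))
  emb <- kwwEmbeddingSpectrum(tau / frameInterval, alpha, nFrames)
  lam <- emb$lambda
  m <- emb$m
  nreal <- nPixels * M
  # complex Gaussian with spectral variances lambda: exact circular cov
  zr <- matrix(rnorm(m * nreal), m, nreal)
  zi <- matrix(rnorm(m * nreal), m, nreal)
  zf <- sqrt(lam / 2) * (zr + 1i * zi)
  z <- mvfft(zf) / sqrt(m)
  intensity <- abs(z[seq_len(nFrames), , drop = FALSE])^2
  if (M > 1L) {
    idx <- rep(seq_len(nPixels), each = M)
    intensity <- t(rowsum(t(intensity), idx)) / M
  }
  counts <- if (photonNoise) {
    matrix(rpois(length(intensity), meanCounts * intensity),
           nFrames, nPixels)
  } else {
    meanCounts * intensity
  }
  list(counts = counts, intensity = intensity,
       truth = list(tau = tau, alpha = alpha, beta = 1 / M),
       eigMin = emb$eigMin)
}

#' Circulant embedding spectrum of the KWW field covariance
#'
#' Builds the circulant extension of r(t) = exp(-(|t|/tau)^alpha) on a ring
#' of length m >= 2 nFrames and returns its eigenvalues (the FFT of the
#' first row). Embeddings with eigenvalues below -1e-10 of the maximum make
#' the length double, up to a limit, then fail loudly; tiny negative values
#' from roundoff are clipped to zero.
#'
#' @param tauFrames time constant in frame units
#' @param alpha KWW exponent in (0, 2]
#' @param nFrames frames needed with exact covariance
#' @param maxDoublings embedding-length doublings to attempt
#' @return list: \code{lambda} (eigenvalues), \code{m} (embedding length),
#'   \code{eigMin} (smallest eigenvalue / largest, before clipping)
#' @export
kwwEmbeddingSpectrum <- function(tauFrames, alpha, nFrames,
                                 maxDoublings = 6) {
  m <- 2^ceiling(log2(max(2 * nFrames, 8)))
  for (i in seq_len(maxDoublings + 1L)) {
    k <- 0:(m - 1)
    dist <- pmin(k, m - k)
    r <- exp(-(dist / tauFrames)^alpha)
    lam <- Re(fft(r))
    eigMin <- min(lam) / max(lam)
    if (eigMin >= -1e-8) {
      lam[lam < 0] <- 0
      return(list(lambda = lam, m = m, eigMin = eigMin))
    }
    m <- 2L * m
  }
  stop("circulant embedding of the KWW covariance is not positive ",
       "definite (alpha = ", alpha, "); embedding length limit reached")
}

# ------------------------------------------------------------ frame stacks --

#' Default synthetic detector geometry
#'
#' A compact geometry whose annuli at the standard analysis momentum
#' transfers (0.05-0.15 1/nm) each contain at least ~50 pixels: 12.4 keV,
#' SDD 0.9 m, 75 um pixels, 48 x 48 detector with a centered beam.
#'
#' @param shape detector shape (nrow, ncol)
#' @param sdd sample-detector distance (m)
#' @return a \linkS4class{DetectorGeometry}
#' @export
syntheticGeometry <- function(shape = c(48, 48), sdd = 0.9) {
  DetectorGeometry(energyKeV = 12.4, sdd = sdd, pixelSize = 75,
                   beamCenter = shape / 2, shape = shape)
}

#' Render a synthetic detector frame stack
#'
#' Places independent speckle realizations of the ballistic model at the
#' annulus pixels of every target momentum transfer; remaining pixels carry
#' static Poisson background at the same mean count rate. Ground-truth
#' parameters, the seed and the configuration are embedded in the stack
#' metadata for recovery tests.
#'
#' @param cfg a \linkS4class{SimConfig}
#' @param geometry a \linkS4class{DetectorGeometry}
#' @param temperature metadata temperature (K)
#' @param fluxDensity metadata flux density ((ph/s)/um^2)
#' @param speedFactor optional per-frame modulation (see
#'   \code{\link{telegraphSpeedFactor}})
#' @param binWidth fractional annulus width per target
#' @return a \linkS4class{FrameStack}; the Q binning used is stored in
#'   \code{metadata$binEdges} / \code{metadata$qBins}
#' @export
renderFrameStack <- function(cfg, geometry = syntheticGeometry(),
                             temperature = NA_real_,
                             fluxDensity = NA_real_, speedFactor = NULL,
                             binWidth = 0.1) {
  stopifnot(is(cfg, "SimConfig"))
  tb <- targetBinEdges(cfg@qTargets, binWidth)
  qmap <- buildQMap(geometry, binEdges = tb$edges)
  qmax <- max(qmap@q)
  qmin <- min(qmap@q[qmap@q > 0])
  pixSets <- lapply(tb$bin, function(b) binPixels(qmap, b))
  short <- vapply(pixSets, length, integer(1)) < 50L
  if (any(short))
    stop("q target(s) ", paste(sort(cfg@qTargets)[short], collapse = ", "),
         " map to fewer than 50 pixels; valid detector Q interval is [",
         signif(qmin, 3), ", ", signif(qmax, 3), "] 1/nm")
  set.seed(cfg@seed)
  nf <- cfg@nFrames
  npixTot <- prod(geometry@shape)
  m <- matrix(0L, nf, npixTot)
  truths <- list()
  qsorted <- sort(cfg@qTargets)
  for (i in seq_along(qsorted)) {
    pix <- pixSets[[i]]
    sim <- simulateBallisticSeries(cfg, qsorted[i], nPixels = length(pix),
                                   speedFactor = speedFactor, seed = NA)
    m[, pix] <- sim$counts
    truths[[i]] <- sim$truth
  }
  bg <- which(!(seq_len(npixTot) %in% unlist(pixSets)))
  m[, bg] <- rpois(nf * length(bg), cfg@meanCounts)
  FrameStack(array(m, c(nf, geometry@shape)),
             timestamps = (seq_len(nf) - 1) * cfg@frameInterval,
             geometry = geometry, temperature = temperature,
             fluxDensity = fluxDensity,
             metadata = list(
               synthetic = TRUE, seed = cfg@seed,
               hydration = cfg@hydration, groundTruth = truths,
               binEdges = tb$edges, qBins = tb$bin,
               qTargets = qsorted,
               modulated = !is.null(speedFactor)))
}

#' Generate a synthetic temperature scan
#'
#' For each temperature: tau0(T) = A exp(Ea/(R T)); the observed constant
#' at flux density F is tau(T) = 1/(1/tau0 + a F). When a heterogeneity
#' schedule is given, a telegraph speed modulation with amplitude
#' \code{hetAmplitude(schedule, T)} is applied on top, mean-rate preserving
#' so tau(T) stays on the Arrhenius-plus-flux curve while the line shape
#' stretches near T*. Ground truths are recorded per stack.
#'
#' @param protocol a \linkS4class{TemperatureProtocol}
#' @param base a \linkS4class{SimConfig}; \code{velocityScale} is set per
#'   temperature so the first (lowest) q target decays with tau(T); seeds
#'   are derived as \code{base@seed + index}
#' @param het optional \linkS4class{HeterogeneitySchedule} (overrides
#'   \code{base@hetSchedule}); NULL disables intermittency
#' @param geometry detector geometry for rendering
#' @param qRef momentum transfer at which tau(T) is anchored (default:
#'   smallest q target)
#' @return list of \linkS4class{FrameStack}, one per temperature
#' @export
generateTemperatureScan <- function(protocol, base = SimConfig(),
                                    het = base@hetSchedule,
                                    geometry = syntheticGeometry(),
                                    qRef = min(base@qTargets)) {
  stopifnot(is(protocol, "TemperatureProtocol"))
  lapply(seq_along(protocol@temperatures), function(i) {
    Tk <- protocol@temperatures[i]
    tau0 <- protocol@tau0Amplitude *
      exp(protocol@activationEnergy * 1000 / (.RGAS * Tk))
    tauObs <- 1 / (1 / tau0 + protocol@couplingA * protocol@fluxDensity)
    cfg <- base
    cfg@velocityScale <- velocityScaleFor(qRef, tauObs)
    cfg@seed <- base@seed + i
    speed <- NULL
    amp <- 0
    if (!is.null(het)) {
      amp <- hetAmplitude(het, Tk)
      set.seed(cfg@seed * 2L + 1L)
      speed <- telegraphSpeedFactor(het, cfg@nFrames, cfg@frameInterval,
                                    amplitude = amp)$speed
    }
    stack <- renderFrameStack(cfg, geometry, temperature = Tk,
                              fluxDensity = protocol@fluxDensity,
                              speedFactor = speed)
    stack@metadata$scanTruth <- list(
      tau0 = tau0, tauObs = tauObs, amplitude = amp,
      A = protocol@tau0Amplitude, Ea = protocol@activationEnergy,
      couplingA = protocol@couplingA, qRef = qRef)
    stack
  })
}
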