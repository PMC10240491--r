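# S4 class definitions. Validity methods enforce the physical invariants;
# user code should go through the constructors and accessors, never slots.

setClassUnion("numericOrNULL", c("numeric", "NULL"))

# ---------------------------------------------------------------- geometry --

#' Detector geometry for small-angle scattering
#'
#' Holds the quantities needed to map detector pixels to momentum transfer:
#' wavelength, sample-detector distance, pixel size, beam center and detector
#' shape. Pixel indexing is 0-based \code{(row, col)} with the origin at the
#' top-left pixel center; the beam center uses the same convention and may
#' lie outside the detector.
#'
#' @slot wavelength photon wavelength (nm)
#' @slot sdd sample-detector distance (m)
#' @slot pixelSize pixel edge length (micrometres)
#' @slot beamCenter numeric(2), beam center as (row, col), 0-based pixels
#' @slot shape integer(2), detector shape as (nrow, ncol)
#' @export
setClass("DetectorGeometry",
  representation(wavelength = "numeric", sdd = "numeric",
                 pixelSize = "numeric", beamCenter = "numeric",
                 shape = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@wavelength) != 1L || !is.finite(object@wavelength) ||
        object@wavelength <= 0)
      msg <- c(msg, "wavelength must be a single positive number (nm)")
    if (length(object@sdd) != 1L || !is.finite(object@sdd) || object@sdd <= 0)
      msg <- c(msg, "sample-detector distance must be positive (m)")
    if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
      msg <- c(msg, "pixel size must be positive (um)")
    if (length(object@beamCenter) != 2L || any(!is.finite(object@beamCenter)))
      msg <- c(msg, "beamCenter must be numeric(2) (row, col)")
    if (length(object@shape) != 2L || any(object@shape < 1L))
      msg <- c(msg, "shape must be two positive integers (nrow, ncol)")
    if (length(msg)) msg else TRUE
  })

#' Construct a DetectorGeometry
#'
#' Supply either the photon energy in keV or the wavelength in nm; the two
#' are related by lambda = 1.23984193 / E.
#'
#' @param energyKeV photon energy (keV); mutually exclusive with
#'   \code{wavelength}
#' @param wavelength photon wavelength (nm)
#' @param sdd sample-detector distance (m)
#' @param pixelSize pixel edge (micrometres)
#' @param beamCenter numeric(2), (row, col), 0-based
#' @param shape integer(2), (nrow, ncol)
#' @return a \linkS4class{DetectorGeometry}
#' @examples
#' geo <- DetectorGeometry(energyKeV = 12.4, sdd = 21.2, pixelSize = 75,
#'                         beamCenter = c(100, 100), shape = c(256, 256))
#' @export
DetectorGeometry <- function(energyKeV = NULL, wavelength = NULL, sdd,
                             pixelSize, beamCenter, shape) {
  if (is.null(wavelength)) {
    if (is.null(energyKeV))
      stop("supply either energyKeV or wavelength")
    wavelength <- .KEV_NM / energyKeV
  } else if (!is.null(energyKeV)) {
    if (abs(wavelength - .KEV_NM / energyKeV) > 1e-6 * wavelength)
      stop("energyKeV and wavelength are inconsistent ",
           "(lambda = 1.23984193/E nm)")
  }
  new("DetectorGeometry", wavelength = wavelength, sdd = sdd,
      pixelSize = pixelSize, beamCenter = as.numeric(beamCenter),
      shape = as.integer(shape))
}

#' Per-pixel momentum-transfer map with bin assignment
#'
#' @slot q per-pixel momentum transfer (1/nm), matrix matching the detector
#' @slot binEdges strictly increasing bin edges (1/nm); bins are half-open
#'   \code{[edge_i, edge_{i+1})}
#' @slot binIndex integer matrix of bin assignments (NA outside all bins or
#'   masked)
#' @slot geometry the generating \linkS4class{DetectorGeometry}
#' @export
setClass("QMap",
  representation(q = "matrix", binEdges = "numeric", binIndex = "matrix",
                 geometry = "DetectorGeometry"),
  validity = function(object) {
    msg <- character()
    if (any(object@q < 0, na.rm = TRUE)) msg <- c(msg, "Q must be >= 0")
    if (is.unsorted(object@binEdges, strictly = TRUE))
      msg <- c(msg, "bin edges must be strictly increasing")
    if (!identical(dim(object@q), dim(object@binIndex)))
      msg <- c(msg, "q and binIndex shapes differ")
    if (length(msg)) msg else TRUE
  })

# -------------------------------------------------------------- frame data --

#' Time-ordered stack of detector frames
#'
#' The raw carrier of I(Q, t): photon-count images with timestamps and the
#' metadata needed for analysis (temperature, incident flux density,
#' geometry, pixel mask, provenance).
#'
#' @slot frames integer array [frame, row, col] of photon counts
#' @slot timestamps strictly increasing frame times (s)
#' @slot temperature sample temperature (K)
#' @slot fluxDensity incident flux density ((ph/s)/um^2)
#' @slot geometry a \linkS4class{DetectorGeometry}
#' @slot mask logical matrix, TRUE = pixel used
#' @slot metadata free-form provenance list (sample id, hydration level,
#'   seed and ground truth if synthetic)
#' @export
setClass("FrameStack",
  representation(frames = "array", timestamps = "numeric",
                 temperature = "numeric", fluxDensity = "numeric",
                 geometry = "DetectorGeometry", mask = "matrix",
                 metadata = "list"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@frames)
    if (length(d) != 3L)
      msg <- c(msg, "frames must be a 3-d array [frame, row, col]")
    if (any(object@frames < 0, na.rm = TRUE))
      msg <- c(msg, "photon counts must be >= 0")
    if (length(object@timestamps) != d[1L])
      msg <- c(msg, "one timestamp per frame required")
    if (is.unsorted(object@timestamps, strictly = TRUE))
      msg <- c(msg, "timestamps must be strictly increasing")
    if (!identical(dim(object@mask), d[2:3]))
      msg <- c(msg, "mask shape must match the frames")
    if (!is.logical(object@mask))
      msg <- c(msg, "mask must be logical")
    if (length(msg)) msg else TRUE
  })

#' Construct a FrameStack
#'
#' @param frames integer array [frame, row, col]
#' @param timestamps frame times (s), strictly increasing
#' @param geometry a \linkS4class{DetectorGeometry}
#' @param temperature sample temperature (K)
#' @param fluxDensity incident flux density ((ph/s)/um^2)
#' @param mask logical matrix (default: all pixels used)
#' @param metadata provenance list
#' @return a \linkS4class{FrameStack}
#' @export
FrameStack <- function(frames, timestamps, geometry, temperature = NA_real_,
                       fluxDensity = NA_real_, mask = NULL,
                       metadata = list()) {
  storage.mode(frames) <- "integer"
  if (is.null(mask))
    mask <- matrix(TRUE, dim(frames)[2L], dim(frames)[3L])
  new("FrameStack", frames = frames, timestamps = as.numeric(timestamps),
      temperature = as.numeric(temperature),
      fluxDensity = as.numeric(fluxDensity), geometry = geometry,
      mask = mask, metadata = metadata)
}

#' Azimuthally averaged intensity profile
#'
#' @slot q bin-center momentum transfers (1/nm)
#' @slot intensity mean counts per pixel per frame; NA for empty bins
#' @slot nPixels unmasked pixels per bin
#' @slot perFrame optional matrix [frame, bin] of per-frame profiles
#' @export
setClass("RadialProfile",
  representation(q = "numeric", intensity = "numeric", nPixels = "integer",
                 perFrame = "matrix"),
  validity = function(object) {
    if (length(object@q) != length(object@intensity) ||
        length(object@q) != length(object@nPixels))
      return("q, intensity and nPixels lengths differ")
    if (any(!is.na(object@intensity) & object@nPixels == 0L))
      return("bins without pixels must be NA, not values")
    TRUE
  })

# ------------------------------------------------------------- correlation --

#' Intensity autocorrelation curve g2(Q, t)
#'
#' @slot q momentum transfer of the bin (1/nm)
#' @slot lags lag times (s), strictly increasing
#' @slot g2 correlation values
#' @slot se standard errors (pixel jackknife), NA if unavailable
#' @slot nPixels pixels averaged
#' @slot nFrames frames used
#' @slot frameInterval frame spacing (s)
#' @slot meta provenance list (temperature, flux density, scheme, ...)
#' @export
setClass("G2Curve",
  representation(q = "numeric", lags = "numeric", g2 = "numeric",
                 se = "numeric", nPixels = "integer", nFrames = "integer",
                 frameInterval = "numeric", meta = "list"),
  validity = function(object) {
    msg <- character()
    n <- length(object@lags)
    if (length(object@g2) != n || length(object@se) != n)
      msg <- c(msg, "lags, g2 and se lengths differ")
    if (is.unsorted(object@lags, strictly = TRUE))
      msg <- c(msg, "lags must be strictly increasing")
    if (any(!is.finite(object@g2)))
      msg <- c(msg, "g2 values must be finite")
    if (any(object@se <= 0, na.rm = TRUE))
      msg <- c(msg, "standard errors must be positive where defined")
    if (length(msg)) msg else TRUE
  })

#' Construct a G2Curve directly (mainly for tests and external data)
#'
#' @param q momentum transfer (1/nm)
#' @param lags lag times (s)
#' @param g2 correlation values
#' @param se standard errors (optional)
#' @param nPixels,nFrames averaging sizes
#' @param frameInterval frame spacing (s)
#' @param meta provenance list
#' @return a \linkS4class{G2Curve}
#' @export
G2Curve <- function(q, lags, g2, se = rep(NA_real_, length(lags)),
                    nPixels = NA_integer_, nFrames = NA_integer_,
                    frameInterval = if (length(lags) > 1L)
                      min(diff(lags)) else NA_real_,
                    meta = list()) {
  new("G2Curve", q = as.numeric(q), lags = as.numeric(lags),
      g2 = as.numeric(g2), se = as.numeric(se),
      nPixels = as.integer(nPixels), nFrames = as.integer(nFrames),
      frameInterval = as.numeric(frameInterval), meta = meta)
}

#' Two-time correlation matrix C(t1, t2)
#'
#' @slot q momentum transfer of the bin (1/nm)
#' @slot times frame times (s) along both axes
#' @slot C the correlation matrix, exactly symmetric by construction
#' @slot nPixels pixels averaged per entry
#' @slot meta provenance list (pre-binning window size if any)
#' @export
setClass("TTCMatrix",
  representation(q = "numeric", times = "numeric", C = "matrix",
                 nPixels = "integer", meta = "list"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@C) != ncol(object@C))
      msg <- c(msg, "C must be square")
    if (length(object@times) != nrow(object@C))
      msg <- c(msg, "times length must match C")
    if (!isTRUE(all.equal(object@C, t(object@C), tolerance = 0)))
      msg <- c(msg, "C must be exactly symmetric")
    if (length(msg)) msg else TRUE
  })

#' Construct a TTCMatrix directly (mainly for tests and external data)
#'
#' @param q momentum transfer (1/nm)
#' @param times frame times (s)
#' @param C symmetric correlation matrix
#' @param nPixels pixels averaged
#' @param meta provenance list
#' @return a \linkS4class{TTCMatrix}
#' @export
TTCMatrix <- function(q, times, C, nPixels = NA_integer_, meta = list()) {
  new(Class = "TTCMatrix", q = as.numeric(q), times = as.numeric(times),
      C = C, nPixels = as.integer(nPixels), meta = meta)
}

#' Speckle contrast estimate
#'
#' @slot beta estimated contrast, in (0, 1.05] (small tolerance for noise)
#' @slot se standard error
#' @slot method "g2-extrapolation" or "variance"
#' @export
setClass("ContrastEstimate",
  representation(beta = "numeric", se = "numeric", method = "character"),
  validity = function(object) {
    if (object@beta <= 0 || object@beta > 1.05)
      return("contrast must lie in (0, 1.05]")
    TRUE
  })

# -------------------------------------------------------------------- fits --

#' Kohlrausch-Williams-Watts fit of a g2 curve
#'
#' Parameters of g2(t) = c + beta * exp(-2 (t/tau)^alpha), so that the
#' underlying field correlation decays as exp(-(t/tau)^alpha).
#'
#' @slot beta speckle contrast
#' @slot baseline the additive baseline c
#' @slot tau time constant (s)
#' @slot alpha KWW exponent
#' @slot se named standard errors
#' @slot cov parameter covariance matrix
#' @slot diagnostics list: residual norm, n points, convergence, flags
#' @export
setClass("KWWFit",
  representation(beta = "numeric", baseline = "numeric", tau = "numeric",
                 alpha = "numeric", se = "numeric", cov = "matrix",
                 diagnostics = "list"),
  validity = function(object) {
    msg <- character()
    if (object@tau <= 0) msg <- c(msg, "tau must be positive")
    if (object@alpha <= 0 || object@alpha > 3)
      msg <- c(msg, "alpha must lie in (0, 3]")
    if (object@beta <= 0) msg <- c(msg, "beta must be positive")
    if (length(msg)) msg else TRUE
  })

#' Linear Q-dispersion fit of the decay rate
#'
#' @slot slope d(1/tau)/dQ (1/s per 1/nm)
#' @slot intercept rate at Q = 0 (1/s)
#' @slot se named standard errors
#' @slot rates data.frame of (q, rate, se) used
#' @slot isBallistic TRUE when |intercept| < 2 SE (rate through the origin)
#' @slot aic AIC of the linear-in-Q and quadratic-in-Q rate models
#' @export
setClass("DispersionFit",
  representation(slope = "numeric", intercept = "numeric", se = "numeric",
                 rates = "data.frame", isBallistic = "logical",
                 aic = "numeric"))

#' Flux-coupling fit 1/tau = 1/tau0 + a F
#'
#' @slot tau0 equilibrium time constant (s)
#' @slot a beam-coupling constant (um^2/ph)
#' @slot se named standard errors (delta method for tau0)
#' @slot perFlux data.frame of (F, tau, se) used
#' @export
setClass("FluxCouplingFit",
  representation(tau0 = "numeric", a = "numeric", se = "numeric",
                 perFlux = "data.frame"),
  validity = function(object) {
    if (object@tau0 <= 0) return("tau0 must be positive")
    if (object@a < 0) return("coupling constant a must be >= 0")
    TRUE
  })

#' Arrhenius fit tau(T) = A exp(Ea / (R T))
#'
#' Activation energies are molar, so the gas constant
#' R = 8.314462618 J/(mol K) is used and Ea is reported in kJ/mol.
#'
#' @slot A amplitude (s)
#' @slot Ea activation energy (kJ/mol)
#' @slot se named standard errors
#' @slot fitData data.frame of (temperature, tau, se) used
#' @export
setClass("ArrheniusFit",
  representation(A = "numeric", Ea = "numeric", se = "numeric",
                 fitData = "data.frame"),
  validity = function(object) {
    if (object@A <= 0) return("amplitude A must be positive")
    if (!is.finite(object@Ea)) return("Ea must be finite")
    TRUE
  })

#' Gaussian-dip fit of the KWW exponent versus temperature
#'
#' alpha(T) = baseline - depth * exp(-(T - Tmin)^2 / (2 width^2))
#'
#' @slot Tmin dip temperature (K)
#' @slot depth dip depth
#' @slot width dip width (K)
#' @slot baseline asymptotic exponent
#' @slot se named standard errors
#' @slot significant TRUE when depth > 2 SE(depth)
#' @slot method "gaussian" or "argmin" (fallback)
#' @export
setClass("MinimumFit",
  representation(Tmin = "numeric", depth = "numeric", width = "numeric",
                 baseline = "numeric", se = "numeric",
                 significant = "logical", method = "character"))

# ----------------------------------------------------------- heterogeneity --

#' Normalized variance chi_T(dt) of a two-time correlation matrix
#'
#' @slot q momentum transfer (1/nm)
#' @slot dt lag grid (s), increasing
#' @slot chi normalized diagonal variance values
#' @slot se block-bootstrap standard errors
#' @slot nEff diagonal samples per lag
#' @slot normalization "beta2", "mean2" or "none"
#' @slot meta provenance list
#' @export
setClass("ChiCurve",
  representation(q = "numeric", dt = "numeric", chi = "numeric",
                 se = "numeric", nEff = "integer",
                 normalization = "character", meta = "list"),
  validity = function(object) {
    if (is.unsorted(object@dt, strictly = TRUE))
      return("dt grid must be increasing")
    if (length(object@chi) != length(object@dt))
      return("chi and dt lengths differ")
    TRUE
  })

#' chi_0 (maximum of chi_T) across temperatures
#'
#' @slot temperatures analyzed temperatures (K)
#' @slot chi0 maximum normalized variance per temperature
#' @slot se standard errors
#' @slot dtPeak lag at the chi_T maximum per temperature (s)
#' @slot Tpeak interpolated temperature of the chi_0 maximum (K)
#' @slot TpeakSE bootstrap standard error of Tpeak (K)
#' @slot significant TRUE when max/median chi0 >= 2
#' @export
setClass("Chi0Series",
  representation(temperatures = "numeric", chi0 = "numeric", se = "numeric",
                 dtPeak = "numeric", Tpeak = "numeric", TpeakSE = "numeric",
                 significant = "logical"),
  validity = function(object) {
    n <- length(object@temperatures)
    if (length(object@chi0) != n) return("one chi0 per temperature required")
    TRUE
  })

# --------------------------------------------------------------- synthetic --

#' Two-state intermittency schedule (telegraph modulation)
#'
#' Models intermittent stress-release dynamics as a stationary telegraph
#' process between a fast and a slow dynamical state. The intermittency
#' strength depends on temperature through a Gaussian amplitude peaked at
#' \code{Tstar}.
#'
#' @slot stateRates exit rates (1/s): c(fast -> slow, slow -> fast); the
#'   stationary fast-state occupancy is rate[2]/(rate[1]+rate[2])
#' @slot fastTau fast-state time constant (s)
#' @slot slowTau slow-state time constant (s), > fastTau
#' @slot Tstar temperature of maximal intermittency (K)
#' @slot width Gaussian width of the amplitude profile (K)
#' @slot maxAmplitude peak intermittency strength in [0, 1]
#' @export
setClass("HeterogeneitySchedule",
  representation(stateRates = "numeric", fastTau = "numeric",
                 slowTau = "numeric", Tstar = "numeric", width = "numeric",
                 maxAmplitude = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@stateRates) != 2L || any(object@stateRates <= 0))
      msg <- c(msg, "two positive switching rates required")
    if (object@fastTau >= object@slowTau)
      msg <- c(msg, "fastTau must be smaller than slowTau")
    if (object@maxAmplitude < 0 || object@maxAmplitude > 1)
      msg <- c(msg, "maxAmplitude must lie in [0, 1]")
    if (object@width <= 0) msg <- c(msg, "width must be positive")
    if (length(msg)) msg else TRUE
  })

#' Construct a HeterogeneitySchedule
#'
#' Defaults model rare fast stress-release bursts in a predominantly slow
#' matrix: fast-state occupancy 0.3 (dwell times 200 s fast, 467 s slow)
#' and a Gaussian intermittency amplitude of width 6 K peaked at 227 K.
#'
#' @param stateRates exit rates (1/s), c(fast->slow, slow->fast)
#' @param fastTau,slowTau state time constants (s)
#' @param Tstar peak temperature (K)
#' @param width Gaussian width (K)
#' @param maxAmplitude peak strength in [0, 1]
#' @return a \linkS4class{HeterogeneitySchedule}
#' @export
HeterogeneitySchedule <- function(stateRates = c(1 / 200, 1 / 467),
                                  fastTau = 26, slowTau = 220,
                                  Tstar = 227, width = 6,
                                  maxAmplitude = 1) {
  new("HeterogeneitySchedule", stateRates = as.numeric(stateRates),
      fastTau = fastTau, slowTau = slowTau, Tstar = Tstar, width = width,
      maxAmplitude = maxAmplitude)
}

setClassUnion("HetScheduleOrNULL", c("HeterogeneitySchedule", "NULL"))

#' Generative specification for synthetic speckle data
#'
#' @slot nScatterers scatterers per speckle realization
#' @slot levyIndex Levy-stable index mu in (0, 2] of the velocity
#'   distribution; the fitted KWW exponent equals mu
#' @slot velocityScale stable scale of the velocities (nm/s); the field
#'   correlation decays as exp(-(velocityScale * q * t)^mu)
#' @slot eventRate Poisson rate (1/s) of velocity redraws per scatterer
#'   (stress-release events); 0 = pure ballistic
#' @slot nModes independent coherence modes M; speckle contrast beta = 1/M
#' @slot meanCounts mean photons per pixel per frame
#' @slot frameInterval frame spacing (s)
#' @slot nFrames frames per stack
#' @slot qTargets momentum transfers to simulate (1/nm)
#' @slot seed RNG seed
#' @slot hydration sample hydration level metadata (g water / g protein)
#' @slot hetSchedule optional \linkS4class{HeterogeneitySchedule}
#' @export
setClass("SimConfig",
  representation(nScatterers = "integer", levyIndex = "numeric",
                 velocityScale = "numeric", eventRate = "numeric",
                 nModes = "integer", meanCounts = "numeric",
                 frameInterval = "numeric", nFrames = "integer",
                 qTargets = "numeric", seed = "integer",
                 hydration = "numeric", hetSchedule = "HetScheduleOrNULL"),
  validity = function(object) {
    msg <- character()
    if (object@levyIndex <= 0 || object@levyIndex > 2)
      msg <- c(msg, "levyIndex must lie in (0, 2]")
    if (object@nModes < 1L) msg <- c(msg, "nModes must be >= 1")
    if (object@meanCounts <= 0) msg <- c(msg, "meanCounts must be positive")
    if (object@frameInterval <= 0)
      msg <- c(msg, "frameInterval must be positive")
    if (any(object@qTargets <= 0)) msg <- c(msg, "q targets must be positive")
    if (object@nScatterers < 2L) msg <- c(msg, "need at least 2 scatterers")
    if (object@velocityScale < 0)
      msg <- c(msg, "velocityScale must be >= 0")
    if (object@eventRate < 0) msg <- c(msg, "eventRate must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Construct a SimConfig
#'
#' @param nScatterers scatterers per realization
#' @param levyIndex velocity Levy index mu in (0, 2]
#' @param velocityScale stable velocity scale (nm/s); see
#'   \code{\link{velocityScaleFor}} to target a time constant at given q
#' @param eventRate velocity-redraw rate (1/s)
#' @param nModes coherence modes (contrast = 1/nModes)
#' @param meanCounts photons/pixel/frame
#' @param frameInterval frame spacing (s)
#' @param nFrames frames
#' @param qTargets momentum transfers (1/nm)
#' @param seed RNG seed
#' @param hydration hydration-level metadata (default 0.28)
#' @param hetSchedule optional \linkS4class{HeterogeneitySchedule}
#' @return a \linkS4class{SimConfig}
#' @export
SimConfig <- function(nScatterers = 32, levyIndex = 1.5,
                      velocityScale = velocityScaleFor(0.1, 100),
                      eventRate = 0, nModes = 4, meanCounts = 60,
                      frameInterval = 2, nFrames = 2000,
                      qTargets = c(0.08, 0.1), seed = 1,
                      hydration = 0.28, hetSchedule = NULL) {
  new("SimConfig", nScatterers = as.integer(nScatterers),
      levyIndex = levyIndex, velocityScale = velocityScale,
      eventRate = eventRate, nModes = as.integer(nModes),
      meanCounts = meanCounts, frameInterval = frameInterval,
      nFrames = as.integer(nFrames), qTargets = as.numeric(qTargets),
      seed = as.integer(seed), hydration = hydration,
      hetSchedule = hetSchedule)
}

#' Velocity scale targeting a decay time at a reference q
#'
#' The ballistic generator decorrelates as exp(-(c q t)^mu); choosing
#' c = 1/(q tau) makes the fitted KWW time constant at momentum transfer q
#' equal tau, with rate linear in q.
#'
#' @param q momentum transfer (1/nm)
#' @param tau target time constant (s)
#' @return velocity scale (nm/s)
#' @export
velocityScaleFor <- function(q, tau) 1 / (q * tau)

#' Temperature protocol of a synthetic scan
#'
#' Equilibrium time constants follow the Arrhenius law
#' tau0(T) = A exp(Ea/(R T)); the observed constant at flux density F is
#' 1/tau = 1/tau0 + a F.
#'
#' @slot temperatures scan temperatures (K), strictly monotone
#' @slot fluxDensity flux density ((ph/s)/um^2)
#' @slot tau0Amplitude Arrhenius amplitude A (s)
#' @slot activationEnergy Ea (kJ/mol)
#' @slot couplingA beam coupling a (um^2/ph)
#' @export
setClass("TemperatureProtocol",
  representation(temperatures = "numeric", fluxDensity = "numeric",
                 tau0Amplitude = "numeric", activationEnergy = "numeric",
                 couplingA = "numeric"),
  validity = function(object) {
    msg <- character()
    dT <- diff(object@temperatures)
    if (length(object@temperatures) < 2L || !(all(dT > 0) || all(dT < 0)))
      msg <- c(msg, "temperatures must be strictly monotone")
    if (object@fluxDensity < 0) msg <- c(msg, "flux density must be >= 0")
    if (object@tau0Amplitude <= 0) msg <- c(msg, "A must be positive")
    if (object@activationEnergy <= 0) msg <- c(msg, "Ea must be positive")
    if (object@couplingA < 0) msg <- c(msg, "coupling a must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Construct a TemperatureProtocol
#'
#' Defaults reproduce the study conditions of a cooling scan at
#' F = 1.5e6 (ph/s)/um^2 with A = 1.8 s, Ea = 9.4 kJ/mol and
#' a = 1.1e-8 um^2/ph, on a grid densified near the expected anomaly.
#'
#' @param temperatures scan grid (K)
#' @param fluxDensity flux density ((ph/s)/um^2)
#' @param tau0Amplitude Arrhenius amplitude A (s)
#' @param activationEnergy Ea (kJ/mol)
#' @param couplingA beam coupling a (um^2/ph)
#' @return a \linkS4class{TemperatureProtocol}
#' @export
TemperatureProtocol <- function(temperatures = c(290, 270, 250, 240, 230,
                                                 225, 220, 210, 195, 180),
                                fluxDensity = 1.5e6, tau0Amplitude = 1.8,
                                activationEnergy = 9.4, couplingA = 1.1e-8) {
  new("TemperatureProtocol", temperatures = as.numeric(temperatures),
      fluxDensity = fluxDensity, tau0Amplitude = tau0Amplitude,
      activationEnergy = activationEnergy, couplingA = couplingA)
}
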