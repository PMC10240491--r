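# Shared fixtures and small analytic helpers for the test suite.
# Everything is generated in code; no binary fixtures.

# analytic intensity autocorrelation of a KWW field decay
analyticG2 <- function(t, tau, alpha, beta, baseline = 1)
  baseline + beta * exp(-2 * (t / tau)^alpha)

# compact synthetic geometry whose q = 0.05..0.15 annuli are populated
testGeometry <- function(shape = c(48, 48))
  syntheticGeometry(shape = shape)

# a tiny valid frame stack with constant counts
constantStack <- function(value = 7L, nFrames = 40L, shape = c(16, 16)) {
  geo <- DetectorGeometry(energyKeV = 12.4, sdd = 0.9, pixelSize = 75,
                          beamCenter = shape / 2, shape = shape)
  FrameStack(array(value, c(nFrames, shape)),
             timestamps = seq_len(nFrames) - 1, geometry = geo,
             temperature = 300, fluxDensity = 1e6)
}

# ballistic pixel series at one q with sensible small defaults
quickBallistic <- function(q = 0.1, tau = 50, mu = 1.5, nFrames = 4000,
                           nPixels = 60, seed = 1, nModes = 4,
                           nScatterers = 32, frameInterval = 1,
                           eventRate = 0, ...) {
  cfg <- SimConfig(nScatterers = nScatterers, levyIndex = mu,
                   velocityScale = velocityScaleFor(q, tau),
                   eventRate = eventRate, nModes = nModes,
                   frameInterval = frameInterval, nFrames = nFrames,
                   qTargets = q, seed = seed)
  simulateBallisticSeries(cfg, q, nPixels = nPixels, ...)
}
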