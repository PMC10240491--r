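# Accessor and show methods.

#' @describeIn qValue momentum transfer of a g2 curve
#' @export
setMethod("qValue", "G2Curve", function(x) x@q)

#' @describeIn qValue momentum transfer of a TTC matrix
#' @export
setMethod("qValue", "TTCMatrix", function(x) x@q)

#' @describeIn qValue momentum transfer of a chi_T curve
#' @export
setMethod("qValue", "ChiCurve", function(x) x@q)

#' @describeIn lagTimes lag grid of a g2 curve
#' @export
setMethod("lagTimes", "G2Curve", function(x) x@lags)

#' @describeIn lagTimes lag grid of a chi_T curve
#' @export
setMethod("lagTimes", "ChiCurve", function(x) x@dt)

#' @describeIn g2Values correlation values
#' @export
setMethod("g2Values", "G2Curve", function(x) x@g2)

#' @describeIn g2Errors jackknife standard errors
#' @export
setMethod("g2Errors", "G2Curve", function(x) x@se)

#' @describeIn corrMatrix the symmetric two-time matrix
#' @export
setMethod("corrMatrix", "TTCMatrix", function(x) x@C)

#' @describeIn frameTimes timestamps of a frame stack
#' @export
setMethod("frameTimes", "FrameStack", function(x) x@timestamps)

#' @describeIn frameTimes frame times of a TTC matrix
#' @export
setMethod("frameTimes", "TTCMatrix", function(x) x@times)

#' @describeIn frameData photon counts of a stack
#' @export
setMethod("frameData", "FrameStack", function(x) x@frames)

#' @describeIn pixelMask pixel mask of a stack
#' @export
setMethod("pixelMask", "FrameStack", function(x) x@mask)

#' @describeIn chiValues normalized variance values
#' @export
setMethod("chiValues", "ChiCurve", function(x) x@chi)

#' @describeIn hetAmplitude Gaussian amplitude profile, maximal at Tstar
#' @export
setMethod("hetAmplitude", "HeterogeneitySchedule",
  function(schedule, temperature) {
    schedule@maxAmplitude *
      exp(-(temperature - schedule@Tstar)^2 / (2 * schedule@width^2))
  })

# coef/vcov interface for the fit classes ------------------------------------

#' @describeIn fitKWW extract c(beta, baseline, tau, alpha)
#' @param object a fit object
#' @export
setMethod("coef", "KWWFit", function(object)
  c(beta = object@beta, baseline = object@baseline, tau = object@tau,
    alpha = object@alpha))

#' @describeIn fitKWW parameter covariance matrix
#' @export
setMethod("vcov", "KWWFit", function(object) object@cov)

#' @describeIn fitFluxCoupling extract c(tau0, a)
#' @param object a fit object
#' @export
setMethod("coef", "FluxCouplingFit", function(object)
  c(tau0 = object@tau0, a = object@a))

#' @describeIn fitArrhenius extract c(A, Ea)
#' @param object a fit object
#' @export
setMethod("coef", "ArrheniusFit", function(object)
  c(A = object@A, Ea = object@Ea))

#' @describeIn fitQDispersion extract c(slope, intercept)
#' @param object a fit object
#' @export
setMethod("coef", "DispersionFit", function(object)
  c(slope = object@slope, intercept = object@intercept))

#' @describeIn locateKWWMinimum extract c(Tmin, depth, width, baseline)
#' @param object a fit object
#' @export
setMethod("coef", "MinimumFit", function(object)
  c(Tmin = object@Tmin, depth = object@depth, width = object@width,
    baseline = object@baseline))

# show methods ----------------------------------------------------------------

setMethod("show", "DetectorGeometry", function(object) {
  cat(sprintf(
    "DetectorGeometry: lambda %.5f nm, SDD %.3g m, pixel %.3g um\n",
    object@wavelength, object@sdd, object@pixelSize))
  cat(sprintf("  shape %d x %d, beam center (%.2f, %.2f) [row, col]\n",
              object@shape[1], object@shape[2], object@beamCenter[1],
              object@beamCenter[2]))
})

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FrameStack: %d frames of %d x %d pixels\n", d[1], d[2], d[3]))
  cat(sprintf("  span %.4g s, T = %s K, F = %s (ph/s)/um^2, %d masked\n",
              diff(range(object@timestamps)),
              format(object@temperature), format(object@fluxDensity),
              sum(!object@mask)))
})

setMethod("show", "G2Curve", function(object) {
  cat(sprintf(
    "G2Curve at Q = %.4g 1/nm: %d lags in [%.4g, %.4g] s (%d px, %d frames)\n",
    object@q, length(object@lags), min(object@lags), max(object@lags),
    object@nPixels, object@nFrames))
})

setMethod("show", "TTCMatrix", function(object) {
  cat(sprintf("TTCMatrix at Q = %.4g 1/nm: %d x %d, span %.4g s (%d px)\n",
              object@q, nrow(object@C), ncol(object@C),
              diff(range(object@times)), object@nPixels))
})

setMethod("show", "KWWFit", function(object) {
  cat(sprintf(
    "KWW fit: beta = %.4g, c = %.4g, tau = %.4g s, alpha = %.4g\n",
    object@beta, object@baseline, object@tau, object@alpha))
  if (all(is.finite(object@se)))
    cat(sprintf("  SE: tau %.3g s, alpha %.3g\n",
                object@se[["tau"]], object@se[["alpha"]]))
})

setMethod("show", "FluxCouplingFit", function(object) {
  cat(sprintf(
    "Flux coupling 1/tau = 1/tau0 + a F: tau0 = %.4g +/- %.2g s, a = %.4g +/- %.2g um^2/ph\n",
    object@tau0, object@se[["tau0"]], object@a, object@se[["a"]]))
})

setMethod("show", "ArrheniusFit", function(object) {
  cat(sprintf(
    "Arrhenius tau = A exp(Ea/RT): A = %.4g +/- %.2g s, Ea = %.4g +/- %.2g kJ/mol\n",
    object@A, object@se[["A"]], object@Ea, object@se[["Ea"]]))
})

setMethod("show", "MinimumFit", function(object) {
  cat(sprintf(
    "KWW-exponent minimum (%s): Tmin = %.4g K, depth = %.3g (%ssignificant)\n",
    object@method, object@Tmin, object@depth,
    if (object@significant) "" else "not "))
})

setMethod("show", "ChiCurve", function(object) {
  cat(sprintf(
    "ChiCurve at Q = %.4g 1/nm: %d lags, normalization %s, max %.4g\n",
    object@q, length(object@dt), object@normalization, max(object@chi)))
})

setMethod("show", "Chi0Series", function(object) {
  cat(sprintf(
    "Chi0Series over %d temperatures: Tpeak = %.4g +/- %.2g K (%ssignificant)\n",
    length(object@temperatures), object@Tpeak, object@TpeakSE,
    if (object@significant) "" else "not "))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d scatterers, mu = %.3g, M = %d modes, %d frames x %.3g s\n",
    object@nScatterers, object@levyIndex, object@nModes, object@nFrames,
    object@frameInterval))
  cat(sprintf("  q targets: %s 1/nm; mean counts %.3g; seed %d; het: %s\n",
              paste(format(object@qTargets), collapse = ", "),
              object@meanCounts, object@seed,
              if (is.null(object@hetSchedule)) "none" else "telegraph"))
})

setMethod("show", "HeterogeneitySchedule", function(object) {
  p <- object@stateRates[2] / sum(object@stateRates)
  cat(sprintf(
    "HeterogeneitySchedule: tau %.3g/%.3g s, fast occupancy %.2f, T* = %.4g K (width %.3g K)\n",
    object@fastTau, object@slowTau, p, object@Tstar, object@width))
})
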