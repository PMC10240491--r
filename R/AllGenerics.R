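# Generics. Accessors are preferred over direct slot access everywhere.

#' Momentum transfer of an object
#' @param x an object with an associated Q value
#' @return momentum transfer (1/nm)
#' @export
setGeneric("qValue", function(x) standardGeneric("qValue"))

#' Lag-time grid of a correlation curve
#' @param x a \linkS4class{G2Curve} or \linkS4class{ChiCurve}
#' @return lag times (s)
#' @export
setGeneric("lagTimes", function(x) standardGeneric("lagTimes"))

#' Correlation values of a g2 curve
#' @param x a \linkS4class{G2Curve}
#' @return numeric vector of g2 values
#' @export
setGeneric("g2Values", function(x) standardGeneric("g2Values"))

#' Standard errors of a g2 curve
#' @param x a \linkS4class{G2Curve}
#' @return numeric vector of standard errors
#' @export
setGeneric("g2Errors", function(x) standardGeneric("g2Errors"))

#' Correlation matrix of a two-time correlation object
#' @param x a \linkS4class{TTCMatrix}
#' @return the symmetric matrix C(t1, t2)
#' @export
setGeneric("corrMatrix", function(x) standardGeneric("corrMatrix"))

#' Frame times of an object
#' @param x a \linkS4class{FrameStack} or \linkS4class{TTCMatrix}
#' @return times (s)
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' Photon-count frames of a stack
#' @param x a \linkS4class{FrameStack}
#' @return integer array [frame, row, col]
#' @export
setGeneric("frameData", function(x) standardGeneric("frameData"))

#' Pixel mask of a stack
#' @param x a \linkS4class{FrameStack}
#' @return logical matrix, TRUE = used
#' @export
setGeneric("pixelMask", function(x) standardGeneric("pixelMask"))

#' chi_T values of a heterogeneity curve
#' @param x a \linkS4class{ChiCurve}
#' @return numeric vector
#' @export
setGeneric("chiValues", function(x) standardGeneric("chiValues"))

#' Intermittency amplitude of a schedule at given temperatures
#' @param schedule a \linkS4class{HeterogeneitySchedule}
#' @param temperature temperatures (K)
#' @return amplitudes in [0, 1]
#' @export
setGeneric("hetAmplitude",
           function(schedule, temperature) standardGeneric("hetAmplitude"))

#' Compute g2 for one momentum-transfer bin
#'
#' g2(t) = <I(t0) I(t0+t)> / (<I(t0)> <I(t0+t)>), averaged over start times
#' t0 and over the unmasked pixels of the bin. The symmetric (two-mean)
#' normalization reduces bias from slow intensity drift and reduces to the
#' classic single-squared-mean form under stationarity. Standard errors are
#' obtained by a leave-one-pixel-out jackknife.
#'
#' @param x a \linkS4class{FrameStack}, or a numeric matrix [frame, pixel]
#'   of intensity series from a single bin
#' @param ... passed to methods; see
#'   \code{\link{computeG2,FrameStack-method}}
#' @return a \linkS4class{G2Curve}
#' @export
setGeneric("computeG2", function(x, ...) standardGeneric("computeG2"))

#' Compute the two-time correlation matrix for one bin
#'
#' C(t1, t2) = <I(t1) I(t2)>_pix / (<I(t1)>_pix <I(t2)>_pix), averaged over
#' pixels only, never over time, so non-stationary and intermittent dynamics
#' remain visible along the diagonal.
#'
#' @param x a \linkS4class{FrameStack} or numeric matrix [frame, pixel]
#' @param ... passed to methods
#' @return a \linkS4class{TTCMatrix}
#' @export
setGeneric("computeTTC", function(x, ...) standardGeneric("computeTTC"))

#' Estimate the speckle contrast beta
#'
#' Default method extrapolates g2 - 1 to zero lag from the shortest lags;
#' the alternative "variance" method uses the per-frame normalized pixel
#' variance corrected for Poisson counting noise,
#' beta = (var(I) - mean(I)) / mean(I)^2.
#'
#' @param x a \linkS4class{FrameStack} or numeric matrix [frame, pixel]
#' @param ... passed to methods
#' @return a \linkS4class{ContrastEstimate}
#' @export
setGeneric("estimateContrast",
           function(x, ...) standardGeneric("estimateContrast"))
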