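# Dynamical heterogeneity from two-time correlation matrices: the
# normalized variance chi_T along the TTC diagonal (an experimentally
# accessible estimator of the four-point dynamic susceptibility), its
# maximum chi_0, the chi_0(T) peak, and the fast timescale at the chi peak.

#' Normalized variance chi_T of a two-time correlation matrix
#'
#' For each lag dt, chi_T(dt) is the variance of C(t, t + dt) along the TTC
#' diagonal (finite-sample n/(n-1) corrected), normalized by the squared
#' speckle contrast so values are comparable across temperatures
#' (alternatives: normalization by the squared diagonal mean, or none).
#' Standard errors come from a moving-block bootstrap over diagonal
#' segments, which respects the serial correlation of the diagonal samples.
#'
#' @param ttc a \linkS4class{TTCMatrix}
#' @param contrast a \linkS4class{ContrastEstimate} (or numeric beta)
#' @param dtGrid lag grid in frames (default: multi-tau grid up to a
#'   quarter of the span)
#' @param normalization "beta2" (default), "mean2" or "none"
#' @param minDiagonal smallest number of diagonal samples to keep a lag
#' @param nBoot bootstrap replicates
#' @param nBlocks diagonal blocks for the bootstrap
#' @return a \linkS4class{ChiCurve}
#' @export
computeChiT <- function(ttc, contrast, dtGrid = NULL,
                        normalization = c("beta2", "mean2", "none"),
                        minDiagonal = 20, nBoot = 200, nBlocks = 8) {
  stopifnot(is(ttc, "TTCMatrix"))
  normalization <- match.arg(normalization)
  beta <- if (is(contrast, "ContrastEstimate")) contrast@beta
          else as.numeric(contrast)
  if (normalization == "beta2" && (!is.finite(beta) || beta <= 0))
    stop("contrast beta must be positive for beta^2 normalization")
  C <- ttc@C
  nf <- nrow(C)
  dt <- median(diff(ttc@times))
  if (is.null(dtGrid)) dtGrid <- multitauLags(nf, maxLag = nf %/% 4)
  dtGrid <- sort(unique(as.integer(dtGrid)))
  usable <- dtGrid <= nf - minDiagonal
  if (!any(usable)) stop("TTC span too short for the requested lags")
  dtGrid <- dtGrid[usable]
  chi <- se <- numeric(length(dtGrid))
  nEff <- integer(length(dtGrid))
  for (k in seq_along(dtGrid)) {
    l <- dtGrid[k]
    d <- C[cbind(seq_len(nf - l), seq_len(nf - l) + l)]
    norm <- switch(normalization,
                   beta2 = beta^2, mean2 = mean(d)^2, none = 1)
    chi[k] <- var(d) / norm
    nEff[k] <- length(d)
    # moving-block bootstrap over diagonal segments
    blockLen <- max(2L, floor(length(d) / nBlocks))
    starts <- seq_len(length(d) - blockLen + 1L)
    nDraw <- ceiling(length(d) / blockLen)
    bs <- vapply(seq_len(nBoot), function(b) {
      idx <- unlist(lapply(sample(starts, nDraw, replace = TRUE),
                           function(s) s:(s + blockLen - 1L)))
      db <- d[idx[seq_along(d)]]
      var(db) / norm
    }, numeric(1))
    se[k] <- sd(bs)
  }
  new("ChiCurve", q = ttc@q, dt = dtGrid * dt, chi = chi, se = se,
      nEff = nEff, normalization = normalization,
      meta = c(ttc@meta, list(beta = beta)))
}

#' Maximum of a chi_T curve
#'
#' @param curve a \linkS4class{ChiCurve}
#' @return list: \code{chi0}, \code{dtPeak} (s), \code{se},
#'   \code{boundary} (TRUE when the maximum sits on the first or last lag)
#'   ; ties resolve to the smaller lag
#' @export
chiMax <- function(curve) {
  stopifnot(is(curve, "ChiCurve"))
  ok <- is.finite(curve@chi)
  if (!any(ok)) stop("chi_T curve has no finite values")
  chi <- curve@chi[ok]
  dt <- curve@dt[ok]
  sev <- curve@se[ok]
  i <- which(chi == max(chi))[1L]  # ties -> smaller dt (grid is increasing)
  list(chi0 = chi[i], dtPeak = dt[i], se = sev[i],
       boundary = i == 1L || i == length(chi))
}

#' chi_0 versus temperature and its peak
#'
#' Assembles the per-temperature maxima of chi_T and locates the peak
#' temperature by a quadratic (three-point Lagrange) interpolation around
#' the discrete argmax; the standard error comes from a parametric
#' bootstrap over the per-temperature chi_0 errors. The peak is flagged
#' significant when max(chi0)/median(chi0) >= 2.
#'
#' @param temperature temperatures (K), at least 5
#' @param curves list of \linkS4class{ChiCurve} matching \code{temperature}
#' @param nBoot bootstrap replicates
#' @return a \linkS4class{Chi0Series}
#' @export
chi0VsTemperature <- function(temperature, curves, nBoot = 500) {
  if (length(temperature) < 5L)
    stop("insufficient span: need at least 5 temperatures")
  stopifnot(length(curves) == length(temperature))
  mx <- lapply(curves, chiMax)
  chi0 <- vapply(mx, `[[`, numeric(1), "chi0")
  se <- vapply(mx, `[[`, numeric(1), "se")
  dtPeak <- vapply(mx, `[[`, numeric(1), "dtPeak")
  ord <- order(temperature)
  Tv <- temperature[ord]
  peakT <- function(vals) {
    i <- which.max(vals[ord])
    if (i == 1L || i == length(Tv)) return(Tv[i])
    .parabolaVertex(Tv[(i - 1):(i + 1)], vals[ord][(i - 1):(i + 1)])
  }
  Tpeak <- peakT(chi0)
  bs <- vapply(seq_len(nBoot), function(b)
    peakT(chi0 + rnorm(length(chi0), 0, ifelse(is.finite(se), se, 0))),
    numeric(1))
  sig <- max(chi0) / median(chi0) >= 2
  new("Chi0Series", temperatures = temperature, chi0 = chi0, se = se,
      dtPeak = dtPeak, Tpeak = Tpeak, TpeakSE = sd(bs), significant = sig)
}

# Vertex of the parabola through three (possibly unevenly spaced) points;
# falls back to the middle abscissa for degenerate (non-concave) triples.
.parabolaVertex <- function(x, y) {
  d1 <- (y[2] - y[1]) / (x[2] - x[1])
  d2 <- (y[3] - y[2]) / (x[3] - x[2])
  curv <- (d2 - d1) / (x[3] - x[1])
  if (!is.finite(curv) || curv >= 0) return(x[2])
  v <- (x[1] + x[2]) / 2 - d1 / (2 * curv)
  min(max(v, min(x)), max(x))
}

#' Fast timescale at the chi_T peak
#'
#' Extracts local g2 curves from diagonal sub-windows of the TTC (width
#' \code{windowFactor} times the peak lag) centered on the epochs that
#' contribute most to the diagonal variance at the peak lag (largest
#' squared deviation of C(t, t+dt_peak) from its mean -- with a minority
#' fast state these are predominantly the decorrelated, fast epochs), fits
#' a KWW decay per window with the contrast held at the global estimate,
#' and returns the mean window time constant.
#'
#' @param ttc a \linkS4class{TTCMatrix}
#' @param curve the matching \linkS4class{ChiCurve}
#' @param contrast a \linkS4class{ContrastEstimate} or numeric beta
#' @param windowFactor window width as a multiple of the peak lag
#' @param maxWindows windows to fit at most
#' @param minWindows required number of usable windows
#' @return list: \code{tauFast} (mean window tau, s), \code{tauWindows},
#'   \code{dtPeak}, \code{windows} (frame centers)
#' @export
timescaleAtChiPeak <- function(ttc, curve, contrast, windowFactor = 4,
                               maxWindows = 8, minWindows = 3) {
  stopifnot(is(ttc, "TTCMatrix"), is(curve, "ChiCurve"))
  beta <- if (is(contrast, "ContrastEstimate")) contrast@beta
          else as.numeric(contrast)
  pk <- chiMax(curve)
  dt <- median(diff(ttc@times))
  lPeak <- max(1L, as.integer(round(pk$dtPeak / dt)))
  C <- ttc@C
  nf <- nrow(C)
  d <- C[cbind(seq_len(nf - lPeak), seq_len(nf - lPeak) + lPeak)]
  # running-mean smoothing for epoch classification only (the pixel noise of
  # a single diagonal sample is comparable to the state separation)
  sw <- max(3L, lPeak)
  dSm <- as.numeric(stats::filter(d, rep(1 / sw, sw), sides = 2))
  dSm[is.na(dSm)] <- d[is.na(dSm)]
  dev <- (dSm - mean(d))^2
  # lower bound keeps a window wide enough for a local decay fit even when
  # the chi peak sits at the shortest lag (homogeneous noise floor)
  half <- max(25L, as.integer(round(windowFactor * lPeak / 2)))
  # two-state segmentation of the smoothed diagonal: k-means with spread
  # initial centers; the lower cluster holds the accelerated (decorrelated)
  # episodes that drive the variance peak
  km <- suppressWarnings(stats::kmeans(
    dSm, centers = matrix(quantile(dSm, c(0.05, 0.95)), 2L)))
  low <- which.min(km$centers)
  withinSD <- sqrt(km$tot.withinss / length(dSm))
  # splitting a plain Gaussian yields a center separation of ~2.7 within-
  # cluster SD; genuine two-state diagonals sit well above 4
  if (abs(diff(as.numeric(km$centers))) < 4 * withinSD) {
    # no resolvable state separation (homogeneous dynamics): take evenly
    # spaced windows so the selection does not chase noise dips
    ctrs <- as.integer(round(seq(half + 1L, nf - half - 1L,
                                 length.out = maxWindows)))
    taus <- numeric(0)
    for (ctr in unique(ctrs)) {
      fit <- .windowKWW(C, ctr, half, lPeak, dt, beta, ttc@q)
      if (!is.null(fit)) taus <- c(taus, fit@tau)
    }
    if (length(taus) < minWindows)
      stop("too few usable variance windows (", length(taus), " < ",
           minWindows, ")")
    return(list(tauFast = mean(taus), tauWindows = taus,
                dtPeak = pk$dtPeak,
                windows = ttc@times[unique(ctrs)], separated = FALSE))
  }
  hot <- km$cluster == low
  runs <- rle(hot)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- data.frame(start = starts[runs$values],
                     end = ends[runs$values])
  if (nrow(cand) == 0L) stop("no variance-contributing epochs found")
  cand$peak <- vapply(seq_len(nrow(cand)), function(i) {
    seg <- cand$start[i]:cand$end[i]
    seg[which.max(dev[seg])]
  }, integer(1))
  cand$score <- dev[cand$peak]
  cand <- cand[order(-cand$score), , drop = FALSE]
  taus <- numeric(0)
  centers <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(taus) >= maxWindows) break
    # center the window on the epoch, between the two diagonal times
    ctr <- (cand$start[i] + cand$end[i]) %/% 2L + lPeak %/% 2L
    w0 <- max(1L, ctr - half)
    w1 <- min(nf, ctr + half)
    if (w1 - w0 < max(6L, 2L * lPeak)) next
    if (length(centers) && any(abs(centers - ctr) < half)) next  # overlap
    # keep windows that lie inside an accelerated epoch: most of their
    # diagonal samples must sit below the diagonal mean
    dIdx <- w0:min(w1, length(d))
    if (mean(km$cluster[dIdx] == low) < 0.8) next
    fit <- .windowKWW(C, ctr, half, lPeak, dt, beta, ttc@q)
    if (is.null(fit)) next
    taus <- c(taus, fit@tau)
    centers <- c(centers, ctr)
  }
  if (length(taus) < minWindows)
    stop("too few usable variance windows (", length(taus), " < ",
         minWindows, ")")
  list(tauFast = mean(taus), tauWindows = taus, dtPeak = pk$dtPeak,
       windows = ttc@times[centers], separated = TRUE)
}

# Local KWW fit on one diagonal block of the TTC: average C(t, t+l) inside
# the window and fit tau, alpha with the contrast and baseline held fixed.
.windowKWW <- function(C, ctr, half, lPeak, dt, beta, q) {
  nf <- nrow(C)
  w0 <- max(1L, ctr - half)
  w1 <- min(nf, ctr + half)
  lagMax <- (w1 - w0) - 2L
  if (lagMax < 6L) return(NULL)
  lags <- unique(pmax(1L, round(exp(seq(log(1), log(lagMax),
                                        length.out = 15)))))
  if (length(lags) < 6L) return(NULL)
  g2loc <- vapply(lags, function(l) {
    idx <- w0:(w1 - l)
    mean(C[cbind(idx, idx + l)])
  }, numeric(1))
  tryCatch(
    fitKWW(G2Curve(q = q, lags = lags * dt, g2 = g2loc,
                   frameInterval = dt),
           fixed = list(baseline = 1, beta = beta),
           init = list(tau = lPeak * dt, alpha = 1.2)),
    error = function(e) NULL, warning = function(w) NULL)
}
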