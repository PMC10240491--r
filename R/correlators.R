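# Intensity correlators: g2, two-time correlation, contrast, lag schemes,
# and a deliberately naive brute-force reference correlator.

# -------------------------------------------------------------- lag schemes --

#' Multi-tau style quasi-logarithmic lag grid
#'
#' Level 0 holds \code{channels} linear lags; every further level doubles
#' the spacing and keeps the upper half of the channels, giving the classic
#' multi-tau grid. Every lag is evaluated with the exact linear estimator
#' (no pre-averaging of frames), so values at all lags are exact; at desk
#' problem sizes the O(N lags) cost is negligible.
#'
#' @param nFrames frames available
#' @param channels channels per level (default 16)
#' @param maxLag largest lag in frames (default nFrames / 2)
#' @return integer vector of lags in frames, strictly increasing
#' @export
multitauLags <- function(nFrames, channels = 16, maxLag = nFrames %/% 2) {
  stopifnot(channels >= 4, nFrames >= 4)
  lags <- seq_len(channels)
  level <- 1L
  repeat {
    step <- 2^level
    nxt <- step * ((channels %/% 2 + 1L):channels)
    if (min(nxt) > maxLag) break
    lags <- c(lags, nxt[nxt <= maxLag])
    level <- level + 1L
    if (step > nFrames) break
  }
  lags <- sort(unique(lags[lags >= 1L & lags <= maxLag]))
  as.integer(lags)
}

#' Linear lag grid
#'
#' @param nFrames frames available
#' @param from,to lag range in frames
#' @param by lag spacing in frames
#' @return integer vector of lags in frames
#' @export
linearLags <- function(nFrames, from = 1, to = nFrames %/% 2, by = 1) {
  as.integer(seq(from, to, by = by))
}

# ------------------------------------------------------------ g2 estimator --

# Workhorse: symmetric-normalization g2 with pixel jackknife.
# I: numeric matrix [frame, pixel]; lags in frames.
.g2Core <- function(I, lags, jackknife = TRUE) {
  if (is.integer(I)) storage.mode(I) <- "double"
  nf <- nrow(I)
  np <- ncol(I)
  lags <- as.integer(lags)
  drop <- lags >= nf
  if (any(drop)) {
    warning(sum(drop), " lag(s) >= n_frames dropped")
    lags <- lags[!drop]
  }
  if (!length(lags)) stop("no usable lags")
  if (!all(colMeans(I) > 0))
    stop("degenerate input: zero mean intensity in ", sum(colMeans(I) <= 0),
         " pixel series")
  g2 <- numeric(length(lags))
  se <- rep(NA_real_, length(lags))
  loo <- if (jackknife && np >= 3L)
    matrix(NA_real_, length(lags), np) else NULL
  for (k in seq_along(lags)) {
    l <- lags[k]
    hd <- seq_len(nf - l)
    num <- colMeans(I[hd, , drop = FALSE] * I[hd + l, , drop = FALSE])
    m1 <- colMeans(I[hd, , drop = FALSE])
    m2 <- colMeans(I[hd + l, , drop = FALSE])
    g2[k] <- mean(num) / (mean(m1) * mean(m2))
    if (!is.null(loo)) {
      sn <- sum(num); s1 <- sum(m1); s2 <- sum(m2)
      gi <- ((sn - num) / (np - 1L)) /
        (((s1 - m1) / (np - 1L)) * ((s2 - m2) / (np - 1L)))
      se[k] <- sqrt((np - 1L) / np * sum((gi - mean(gi))^2))
      loo[k, ] <- gi
    }
  }
  se[!is.na(se) & se <= 0] <- NA_real_
  list(lags = lags, g2 = g2, se = se, loo = loo)
}

#' @describeIn computeG2 g2 from a matrix of single-bin pixel intensity
#'   series
#' @param lags lag grid in frames (default \code{\link{multitauLags}})
#' @param frameInterval frame spacing (s)
#' @param q momentum transfer label (1/nm)
#' @param jackknife compute leave-one-pixel-out standard errors
#' @param meta provenance list stored on the curve
#' @export
setMethod("computeG2", "matrix",
  function(x, lags = multitauLags(nrow(x)), frameInterval = 1, q = NA_real_,
           jackknife = TRUE, meta = list(), ...) {
    if (nrow(x) < 2L) stop("need at least 2 frames")
    r <- .g2Core(x, lags, jackknife)
    # leave-one-pixel-out curves ride along so fits can jackknife their
    # parameter errors (lag-correlated residuals defeat the nls vcov)
    if (!is.null(r$loo)) meta$looG2 <- r$loo
    G2Curve(q = q, lags = r$lags * frameInterval, g2 = r$g2, se = r$se,
            nPixels = ncol(x), nFrames = nrow(x),
            frameInterval = frameInterval, meta = meta)
  })

#' @describeIn computeG2 g2 for one Q bin of a frame stack
#' @param qmap a \linkS4class{QMap}
#' @param qbin bin index into the Q-map bin edges
#' @export
setMethod("computeG2", "FrameStack",
  function(x, qmap, qbin, lags = NULL, jackknife = TRUE, ...) {
    I <- .binSeries(x, qmap, qbin)
    if (is.null(lags)) lags <- multitauLags(nrow(I))
    dt <- .frameIntervalOf(x)
    qc <- .binCenter(qmap, qbin)
    callGeneric(I, lags = lags, frameInterval = dt, q = qc,
                jackknife = jackknife,
                meta = list(temperature = x@temperature,
                            fluxDensity = x@fluxDensity, qbin = qbin))
  })

.frameIntervalOf <- function(stack) {
  dt <- diff(stack@timestamps)
  if (length(dt) == 0L) return(NA_real_)
  median(dt)
}

.binCenter <- function(qmap, qbin)
  (qmap@binEdges[qbin] + qmap@binEdges[qbin + 1L]) / 2

# pixel series of one bin as [frame, pixel]
.binSeries <- function(stack, qmap, qbin, minPixels = 10L) {
  pix <- binPixels(qmap, qbin, stack@mask)
  if (length(pix) < minPixels)
    stop("Q bin ", qbin, " has ", length(pix), " unmasked pixels (< ",
         minPixels, ")")
  nf <- dim(stack@frames)[1L]
  matrix(as.numeric(matrix(stack@frames, nrow = nf)[, pix]), nf,
         length(pix))
}

#' Brute-force reference correlator
#'
#' Computes the identical symmetric-normalization g2 estimator by explicit
#' accumulation loops over start times and pixels. Exists purely as an
#' independent oracle for the production correlator; O(N) per lag and slow
#' on purpose.
#'
#' @param I numeric matrix [frame, pixel]
#' @param lags lag grid in frames
#' @return numeric vector of g2 values at the requested lags
#' @export
bruteForceG2 <- function(I, lags) {
  nf <- nrow(I)
  np <- ncol(I)
  out <- numeric(length(lags))
  for (k in seq_along(lags)) {
    l <- lags[k]
    num <- 0; den1 <- 0; den2 <- 0; n <- 0
    for (p in seq_len(np)) {
      for (t0 in seq_len(nf - l)) {
        num <- num + I[t0, p] * I[t0 + l, p]
        den1 <- den1 + I[t0, p]
        den2 <- den2 + I[t0 + l, p]
        n <- n + 1
      }
    }
    out[k] <- (num / n) / ((den1 / n) * (den2 / n))
  }
  out
}

# --------------------------------------------------------------------- TTC --

#' @describeIn computeTTC TTC from a matrix of single-bin pixel series
#' @param frameInterval frame spacing (s)
#' @param q momentum transfer label (1/nm)
#' @param maxFrames above this, frames are pre-averaged in non-overlapping
#'   windows to bound the matrix size (window size recorded in \code{meta})
#' @param meta provenance list
#' @export
setMethod("computeTTC", "matrix",
  function(x, frameInterval = 1, q = NA_real_, maxFrames = 4000,
           meta = list(), ...) {
    if (is.integer(x)) storage.mode(x) <- "double"
    nf <- nrow(x)
    if (nf < 2L) stop("need at least 2 frames")
    if (!all(colMeans(x) > 0))
      stop("degenerate input: zero mean intensity in bin")
    win <- 1L
    times <- (seq_len(nf) - 1) * frameInterval
    if (nf > maxFrames) {
      win <- as.integer(ceiling(nf / maxFrames))
      nw <- nf %/% win
      grp <- rep(seq_len(nw), each = win)
      x <- rowsum(x[seq_len(nw * win), , drop = FALSE], grp) / win
      times <- rowsum(times[seq_len(nw * win)], grp)[, 1L] / win
      nf <- nw
      meta$preBinWindow <- win
    }
    np <- ncol(x)
    num <- tcrossprod(x) / np
    mu <- rowMeans(x)
    C <- num / outer(mu, mu)
    C <- (C + t(C)) / 2  # enforce exact symmetry against FP noise
    # Class= spelled out: a slot named "C" would otherwise partially match it
    new(Class = "TTCMatrix", q = as.numeric(q), times = times, C = C,
        nPixels = as.integer(np), meta = meta)
  })

#' @describeIn computeTTC TTC for one Q bin of a frame stack
#' @param qmap a \linkS4class{QMap}
#' @param qbin bin index
#' @export
setMethod("computeTTC", "FrameStack",
  function(x, qmap, qbin, maxFrames = 4000, ...) {
    I <- .binSeries(x, qmap, qbin)
    callGeneric(I, frameInterval = .frameIntervalOf(x),
                q = .binCenter(qmap, qbin), maxFrames = maxFrames,
                meta = list(temperature = x@temperature,
                            fluxDensity = x@fluxDensity, qbin = qbin))
  })

#' Average a TTC matrix along its diagonal into a g2 curve
#'
#' For each lag dt, averages C(t, t + dt) over t. Under stationarity this
#' reproduces the time-averaged g2 estimator (up to the different
#' normalization windows), which is the estimator-consistency check used
#' in the test suite.
#'
#' @param ttc a \linkS4class{TTCMatrix}
#' @param lags lag grid in frames (default: multi-tau over the span)
#' @return a \linkS4class{G2Curve} (standard errors from the scatter along
#'   the diagonal)
#' @export
ttcDiagonalAverage <- function(ttc, lags = NULL) {
  C <- ttc@C
  nf <- nrow(C)
  dt <- if (nf > 1L) median(diff(ttc@times)) else NA_real_
  if (is.null(lags)) lags <- multitauLags(nf)
  lags <- lags[lags < nf]
  g2 <- numeric(length(lags))
  se <- numeric(length(lags))
  for (k in seq_along(lags)) {
    l <- lags[k]
    d <- C[cbind(seq_len(nf - l), seq_len(nf - l) + l)]
    g2[k] <- mean(d)
    se[k] <- sd(d) / sqrt(length(d))
  }
  ok <- is.finite(se) & se > 0
  se[!ok] <- NA_real_
  G2Curve(q = ttc@q, lags = lags * dt, g2 = g2, se = se,
          nPixels = ttc@nPixels, nFrames = nf, frameInterval = dt,
          meta = c(ttc@meta, list(source = "ttc-diagonal")))
}

# ---------------------------------------------------------------- contrast --

#' @describeIn estimateContrast contrast from single-bin pixel series
#' @param method "g2" (short-lag extrapolation, default) or "variance"
#'   (Poisson-corrected per-frame normalized variance)
#' @param frameInterval frame spacing (s)
#' @param nExtrapolate lags used by the g2 extrapolation
#' @export
setMethod("estimateContrast", "matrix",
  function(x, method = c("g2", "variance"), frameInterval = 1,
           nExtrapolate = 4, ...) {
    method <- match.arg(method)
    if (method == "g2") {
      lags <- seq_len(max(2L, nExtrapolate))
      curve <- computeG2(x, lags = lags, frameInterval = 1,
                         jackknife = TRUE)
      y <- curve@g2 - 1
      fit <- lm(y ~ curve@lags)
      beta <- unname(coef(fit)[1L])
      se <- sqrt(diag(vcov(fit)))[1L]
    } else {
      mu <- rowMeans(x)
      v <- apply(x, 1L, var)
      b <- (v - mu) / mu^2   # Poisson shot-noise corrected
      beta <- mean(b)
      se <- sd(b) / sqrt(length(b))
    }
    if (!is.finite(beta) || beta <= 0 || beta <= 2 * se)
      stop("no resolvable speckle contrast (beta_hat = ", signif(beta, 3),
           " +/- ", signif(se, 3),
           "): over-masking or pure noise input")
    new("ContrastEstimate", beta = min(beta, 1.05), se = unname(se),
        method = if (method == "g2") "g2-extrapolation" else "variance")
  })

#' @describeIn estimateContrast contrast for one Q bin of a frame stack
#' @param qmap a \linkS4class{QMap}
#' @param qbin bin index
#' @export
setMethod("estimateContrast", "FrameStack",
  function(x, qmap, qbin, method = c("g2", "variance"), ...) {
    I <- .binSeries(x, qmap, qbin)
    callGeneric(I, method = method, frameInterval = .frameIntervalOf(x))
  })
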