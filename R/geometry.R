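# Detector geometry: Q-mapping, azimuthal averaging and mask construction.

.pixelRadii <- function(geometry) {
  # radial distance (m) of each pixel center from the beam center
  nr <- geometry@shape[1L]
  nc <- geometry@shape[2L]
  dr <- (seq_len(nr) - 1) - geometry@beamCenter[1L]
  dc <- (seq_len(nc) - 1) - geometry@beamCenter[2L]
  ps <- geometry@pixelSize * 1e-6
  sqrt(outer(dr^2, dc^2, `+`)) * ps
}

.pixelAzimuth <- function(geometry) {
  # azimuth (degrees in [0, 360)) measured from the +col axis,
  # increasing towards +row (detector row index grows downwards)
  nr <- geometry@shape[1L]
  nc <- geometry@shape[2L]
  dr <- (seq_len(nr) - 1) - geometry@beamCenter[1L]
  dc <- (seq_len(nc) - 1) - geometry@beamCenter[2L]
  ang <- atan2(outer(dr, rep(1, nc)), outer(rep(1, nr), dc)) * 180 / pi
  (ang + 360) %% 360
}

#' Momentum transfer of a radial detector position
#'
#' Q = (4 pi / lambda) sin(theta) with 2 theta = arctan(r / SDD). The exact
#' trigonometric form is used (no small-angle approximation).
#'
#' @param r radial distance in the detector plane (m)
#' @param geometry a \linkS4class{DetectorGeometry}
#' @return momentum transfer (1/nm)
#' @export
qOfRadius <- function(r, geometry) {
  (4 * pi / geometry@wavelength) * sin(atan2(r, geometry@sdd) / 2)
}

#' Build a per-pixel Q map with bin assignment
#'
#' Assigns every pixel a momentum transfer from the exact scattering
#' trigonometry and bins them into half-open intervals
#' \code{[edge_i, edge_{i+1})}.
#'
#' @param geometry a \linkS4class{DetectorGeometry}
#' @param binEdges strictly increasing bin edges (1/nm); default: 30
#'   log-spaced bins over the populated Q range (excluding Q = 0)
#' @param nBins number of default log-spaced bins
#' @return a \linkS4class{QMap}
#' @examples
#' geo <- DetectorGeometry(energyKeV = 12.4, sdd = 1.8, pixelSize = 75,
#'                         beamCenter = c(48, 48), shape = c(96, 96))
#' qm <- buildQMap(geo)
#' @export
buildQMap <- function(geometry, binEdges = NULL, nBins = 30) {
  stopifnot(is(geometry, "DetectorGeometry"))
  q <- qOfRadius(.pixelRadii(geometry), geometry)
  if (is.null(binEdges)) {
    qpos <- q[q > 0]
    binEdges <- exp(seq(log(max(min(qpos), max(qpos) * 1e-3)),
                        log(max(qpos) * (1 + 1e-9)), length.out = nBins + 1))
  }
  idx <- findInterval(q, binEdges, left.open = FALSE, rightmost.closed = FALSE)
  idx[idx == 0L | idx > length(binEdges) - 1L] <- NA_integer_
  binIndex <- matrix(as.integer(idx), nrow(q), ncol(q))
  new("QMap", q = q, binEdges = binEdges, binIndex = binIndex,
      geometry = geometry)
}

#' Bin edges for a set of target Q values
#'
#' Each target gets one annulus bin of fractional width \code{width}
#' (default 10 percent of the center), the convention used for the analysis
#' bins at 0.08 and 0.1 1/nm.
#'
#' @param qTargets bin centers (1/nm)
#' @param width full fractional width of each bin
#' @return list with \code{edges} (concatenated) and \code{bin} (index of
#'   each target's bin among the edges)
#' @export
targetBinEdges <- function(qTargets, width = 0.1) {
  qTargets <- sort(qTargets)
  lo <- qTargets * (1 - width / 2)
  hi <- qTargets * (1 + width / 2)
  if (any(lo[-1] < hi[-length(hi)]))
    stop("q targets too close: annulus bins of width ", width, " overlap")
  edges <- as.numeric(rbind(lo, hi))
  list(edges = edges, bin = seq_along(qTargets) * 2L - 1L)
}

#' Pixels belonging to one Q bin
#'
#' @param qmap a \linkS4class{QMap}
#' @param bin bin index (into the bin-edge intervals)
#' @param mask optional logical matrix; FALSE pixels are excluded
#' @return integer vector of linear (column-major) pixel indices
#' @export
binPixels <- function(qmap, bin, mask = NULL) {
  sel <- !is.na(qmap@binIndex) & qmap@binIndex == bin
  if (!is.null(mask)) sel <- sel & mask
  which(sel)
}

#' Azimuthally averaged intensity profile
#'
#' Per-bin mean photon counts over unmasked pixels, averaged over frames.
#' Empty bins are reported as NA, never as silent zeros.
#'
#' @param stack a \linkS4class{FrameStack}
#' @param qmap a \linkS4class{QMap}
#' @param perFrame also return per-frame profiles (stability monitoring)
#' @param sector optional azimuthal sector \code{c(from, to)} in degrees;
#'   only pixels whose azimuth lies in [from, to) are used
#' @return a \linkS4class{RadialProfile}
#' @export
azimuthalAverage <- function(stack, qmap, perFrame = FALSE, sector = NULL) {
  stopifnot(is(stack, "FrameStack"), is(qmap, "QMap"))
  nf <- dim(stack@frames)[1L]
  nbin <- length(qmap@binEdges) - 1L
  keep <- stack@mask & !is.na(qmap@binIndex)
  if (!is.null(sector)) {
    az <- .pixelAzimuth(stack@geometry)
    keep <- keep & az >= sector[1L] & az < sector[2L]
  }
  pix <- which(keep)
  bins <- qmap@binIndex[pix]
  m <- matrix(stack@frames, nrow = nf)[, pix, drop = FALSE]
  npix <- tabulate(bins, nbins = nbin)
  pixMean <- colMeans(m)
  total <- vapply(seq_len(nbin), function(b)
    sum(pixMean[bins == b]), numeric(1))
  intensity <- ifelse(npix > 0L, total / pmax(npix, 1L), NA_real_)
  pf <- matrix(numeric(0), 0, 0)
  if (perFrame) {
    pf <- matrix(NA_real_, nf, nbin)
    for (b in seq_len(nbin)) {
      cols <- which(bins == b)
      if (length(cols))
        pf[, b] <- rowMeans(m[, cols, drop = FALSE])
    }
  }
  centers <- (qmap@binEdges[-1] + qmap@binEdges[-(nbin + 1L)]) / 2
  new("RadialProfile", q = centers, intensity = intensity,
      nPixels = as.integer(npix), perFrame = pf)
}

#' Mask rule specification
#'
#' @param badPixels optional logical matrix (TRUE = bad) or 2-column
#'   (row, col) 1-based index matrix of static bad pixels
#' @param hotPixelK hot-pixel rule: mask pixels whose time-mean exceeds
#'   \code{hotPixelK} times the median of their Q-annulus (NULL disables)
#' @param sectors list of azimuthal intervals \code{c(from, to)} in degrees
#'   to remove (streak masks)
#' @return a mask rule list for \code{\link{buildMask}}
#' @export
maskRules <- function(badPixels = NULL, hotPixelK = 50, sectors = list()) {
  list(badPixels = badPixels, hotPixelK = hotPixelK, sectors = sectors)
}

#' Build a reproducible pixel mask
#'
#' Combines a static bad-pixel map, a hot-pixel rule (pixel time-mean
#' greater than k times the median of its Q-annulus) and user-drawn angular
#' sector masks for diffraction streaks. TRUE means the pixel is used.
#'
#' @param stack a \linkS4class{FrameStack}
#' @param rules a \code{\link{maskRules}} list; empty rules give an all-TRUE
#'   mask
#' @param qmap optional \linkS4class{QMap} for the hot-pixel annuli (built
#'   from the stack geometry when absent)
#' @return logical matrix
#' @export
buildMask <- function(stack, rules = maskRules(hotPixelK = NULL),
                      qmap = NULL) {
  stopifnot(is(stack, "FrameStack"))
  d <- dim(stack@frames)[2:3]
  mask <- matrix(TRUE, d[1L], d[2L])
  if (!is.null(rules$badPixels)) {
    bp <- rules$badPixels
    if (is.matrix(bp) && is.logical(bp)) {
      mask[bp] <- FALSE
    } else {
      mask[as.matrix(bp)] <- FALSE
    }
  }
  if (length(rules$sectors)) {
    az <- .pixelAzimuth(stack@geometry)
    for (s in rules$sectors)
      mask[az >= s[1L] & az < s[2L]] <- FALSE
  }
  if (!is.null(rules$hotPixelK)) {
    if (is.null(qmap)) qmap <- buildQMap(stack@geometry)
    nf <- dim(stack@frames)[1L]
    pixMean <- colMeans(matrix(stack@frames, nrow = nf))
    bins <- as.integer(qmap@binIndex)
    ok <- !is.na(bins)
    med <- tapply(pixMean[ok], bins[ok], median)
    annMed <- rep(NA_real_, length(pixMean))
    annMed[ok] <- med[as.character(bins[ok])]
    hot <- ok & annMed > 0 & pixMean > rules$hotPixelK * annMed
    mask[matrix(hot, d[1L], d[2L])] <- FALSE
  }
  mask
}

#' Warn about Q bins decimated by a mask
#'
#' @param qmap a \linkS4class{QMap}
#' @param mask logical matrix
#' @param threshold warn when more than this fraction of a bin is removed
#' @return invisibly, the per-bin surviving fraction
#' @export
checkMaskCoverage <- function(qmap, mask, threshold = 0.9) {
  nbin <- length(qmap@binEdges) - 1L
  tot <- tabulate(qmap@binIndex[!is.na(qmap@binIndex)], nbins = nbin)
  left <- tabulate(qmap@binIndex[!is.na(qmap@binIndex) & mask], nbins = nbin)
  frac <- ifelse(tot > 0, left / tot, NA_real_)
  bad <- which(!is.na(frac) & (1 - frac) > threshold & tot > 0)
  if (length(bad))
    warning("mask removes more than ", round(100 * threshold),
            "% of Q bin(s) ", paste(bad, collapse = ", "))
  invisible(frac)
}
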