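# Frame-stack file I/O.
#
# FrameStacks are stored in a versioned plain-text container ("#XPCSFS v1"):
#   line 1: magic + schema version
#   line 2: "#meta "  + one-line JSON (geometry, temperature, flux, metadata)
#   line 3: "#time "  + timestamps (s, full double precision)
#   line 4: "#mask "  + 0/1 per pixel, column-major
#   lines 5..: one whitespace-separated row of integer counts per frame,
#              pixels in column-major (row fastest) order.
# The round trip is lossless for counts, timestamps and metadata.

.XFS_MAGIC <- "#XPCSFS v1"
.XFS_REQUIRED <- c("wavelength", "sdd", "pixelSize", "beamCenter", "shape",
                   "temperature", "fluxDensity")

#' Write a FrameStack to a plain-text container
#'
#' @param stack a \linkS4class{FrameStack}
#' @param path output file path
#' @return invisibly, \code{path}
#' @seealso \code{\link{readFrameStack}}
#' @export
writeFrameStack <- function(stack, path) {
  stopifnot(is(stack, "FrameStack"))
  g <- stack@geometry
  meta <- list(wavelength = g@wavelength, sdd = g@sdd,
               pixelSize = g@pixelSize, beamCenter = g@beamCenter,
               shape = g@shape, temperature = stack@temperature,
               fluxDensity = stack@fluxDensity, metadata = stack@metadata)
  con <- file(path, "w")
  writeLines(c(
    .XFS_MAGIC,
    paste0("#meta ", as.character(jsonlite::toJSON(
      meta, auto_unbox = TRUE, digits = NA, null = "null", na = "null"))),
    paste0("#time ", paste(sprintf("%.17g", stack@timestamps),
                           collapse = " ")),
    paste0("#mask ", paste(as.integer(stack@mask), collapse = " "))), con)
  close(con)
  nf <- dim(stack@frames)[1L]
  m <- matrix(stack@frames, nrow = nf)
  data.table::fwrite(data.table::as.data.table(m), file = path,
                     append = TRUE, sep = " ", col.names = FALSE)
  invisible(path)
}

#' Read a FrameStack from a plain-text container
#'
#' Schema and invariants are enforced at read time: missing required
#' metadata raises an explicit schema error listing the absent fields, and
#' non-monotone timestamps are rejected.
#'
#' @param path file written by \code{\link{writeFrameStack}}
#' @return a \linkS4class{FrameStack}
#' @export
readFrameStack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- readLines(path, n = 4L)
  if (length(hdr) < 4L || hdr[1L] != .XFS_MAGIC)
    stop("schema error: not an XPCSFS v1 frame-stack file: ", path)
  if (!startsWith(hdr[2L], "#meta ") || !startsWith(hdr[3L], "#time ") ||
      !startsWith(hdr[4L], "#mask "))
    stop("schema error: malformed XPCSFS header in ", path)
  meta <- jsonlite::fromJSON(sub("^#meta ", "", hdr[2L]),
                             simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  missingFields <- setdiff(.XFS_REQUIRED, names(meta))
  if (length(missingFields))
    stop("schema error: missing required metadata field(s): ",
         paste(missingFields, collapse = ", "))
  timestamps <- as.numeric(strsplit(sub("^#time ", "", hdr[3L]), " ",
                                    fixed = TRUE)[[1L]])
  maskVec <- as.integer(strsplit(sub("^#mask ", "", hdr[4L]), " ",
                                 fixed = TRUE)[[1L]])
  shape <- as.integer(meta$shape)
  dt <- data.table::fread(path, skip = 4L, sep = " ", header = FALSE,
                          colClasses = "integer")
  m <- as.matrix(dt)
  dimnames(m) <- NULL
  if (ncol(m) != prod(shape) || nrow(m) != length(timestamps))
    stop("schema error: frame table shape (", nrow(m), " x ", ncol(m),
         ") disagrees with header (", length(timestamps), " x ",
         prod(shape), ")")
  geometry <- new("DetectorGeometry", wavelength = meta$wavelength,
                  sdd = meta$sdd, pixelSize = meta$pixelSize,
                  beamCenter = as.numeric(meta$beamCenter), shape = shape)
  md <- meta$metadata
  if (is.null(md)) md <- list()
  scalarOrNA <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  FrameStack(array(m, c(nrow(m), shape[1L], shape[2L])),
             timestamps = timestamps, geometry = geometry,
             temperature = scalarOrNA(meta$temperature),
             fluxDensity = scalarOrNA(meta$fluxDensity),
             mask = matrix(maskVec == 1L, shape[1L], shape[2L]),
             metadata = md)
}

#' Write a g2 curve to CSV
#'
#' Header comments carry units and provenance; columns are lag (s), g2 and
#' the jackknife standard error.
#'
#' @param curve a \linkS4class{G2Curve}
#' @param path output file
#' @return invisibly, \code{path}
#' @export
writeG2Csv <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# g2 curve at Q = %.6g 1/nm", curve@q),
    sprintf("# n_pixels = %d, n_frames = %d, frame_interval_s = %.6g",
            curve@nPixels, curve@nFrames, curve@frameInterval),
    "# columns: lag_s, g2, se"), con)
  write.table(data.frame(lag_s = curve@lags, g2 = curve@g2, se = curve@se),
              con, sep = ",", row.names = FALSE, col.names = TRUE,
              quote = FALSE)
  invisible(path)
}

#' Write a two-time correlation matrix to CSV
#'
#' Row/column times (s) are written as the first column and header row;
#' comment lines carry the Q bin and pre-binning provenance.
#'
#' @param ttc a \linkS4class{TTCMatrix}
#' @param path output file
#' @return invisibly, \code{path}
#' @export
writeTTCCsv <- function(ttc, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# two-time correlation matrix at Q = %.6g 1/nm", ttc@q),
    sprintf("# n_pixels = %d, pre_bin_window = %s", ttc@nPixels,
            if (is.null(ttc@meta$preBinWindow)) "1"
            else ttc@meta$preBinWindow),
    "# first row/column: frame times (s)"), con)
  m <- cbind(ttc@times, ttc@C)
  write.table(rbind(c(NA, ttc@times), m), con, sep = ",",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a chi_T curve to CSV
#'
#' @param curve a \linkS4class{ChiCurve}
#' @param path output file
#' @return invisibly, \code{path}
#' @export
writeChiCsv <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# chi_T curve at Q = %.6g 1/nm", curve@q),
    sprintf("# normalization = %s", curve@normalization),
    "# columns: dt_s, chi_T, se, n_effective"), con)
  write.table(data.frame(dt_s = curve@dt, chi = curve@chi, se = curve@se,
                         n_effective = curve@nEff),
              con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a radial profile to CSV
#'
#' @param profile a \linkS4class{RadialProfile}
#' @param path output file
#' @return invisibly, \code{path}
#' @export
writeProfileCsv <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# azimuthally averaged intensity profile",
               "# columns: q_invnm, intensity_counts_per_pixel, n_pixels"),
             con)
  write.table(data.frame(q_invnm = profile@q,
                         intensity = profile@intensity,
                         n_pixels = profile@nPixels),
              con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
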