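# End-to-end analyses: flux-dependence experiment and temperature scan.
# Both are driven by a plain config list (or YAML file), write all
# artifacts to an output directory, and return a report bundle whose
# manifest makes deterministic stages re-runnable bit-identically.

#' Default flux-experiment configuration
#'
#' Six flux densities spanning 0-90 percent attenuation of
#' Fmax = 4.4e6 (ph/s)/um^2, with ground-truth equilibrium constant
#' tau0 = 336 s, coupling a = 1.1e-8 um^2/ph and KWW exponent 1.5 at
#' Q = 0.08 1/nm (room-temperature study conditions).
#'
#' @param seed RNG seed
#' @return config list for \code{\link{runFluxExperiment}}
#' @export
fluxExperimentConfig <- function(seed = 1) {
  list(
    mode = "simulate",
    fluxDensities = (1 - seq(0, 0.9, length.out = 6)) * 4.4e6,
    tau0 = 336, couplingA = 1.1e-8, alpha = 1.5, q = 0.08,
    nPixels = 150, nFrames = 4096, frameInterval = 2,
    nModes = 4, meanCounts = 60, generator = "oracle",
    nScatterers = 32, seed = seed)
}

#' Run the flux-dependence analysis end to end
#'
#' Simulates (or loads) intensity series at several flux densities, then:
#' per-flux g2, KWW fits, flux-coupling fit 1/tau = 1/tau0 + a F, and the
#' rescaled collapse t / (1 + a F tau0). All artifacts (g2 CSVs, fit JSON,
#' manifest) are written to \code{outDir}.
#'
#' @param config list as from \code{\link{fluxExperimentConfig}}, or a path
#'   to an equivalent YAML file
#' @param outDir output directory (created); NULL skips file output
#' @return report bundle list: \code{g2Curves}, \code{kwwFits},
#'   \code{fluxFit} (\linkS4class{FluxCouplingFit}), \code{collapse},
#'   \code{manifest}, \code{files}
#' @export
runFluxExperiment <- function(config = fluxExperimentConfig(),
                              outDir = NULL) {
  config <- .loadConfig(config, fluxExperimentConfig())
  flux <- config$fluxDensities
  if (length(unique(flux)) < 3L)
    stop("config error: need at least 3 distinct flux densities")
  curves <- list()
  fits <- list()
  for (i in seq_along(flux)) {
    tauF <- 1 / (1 / config$tau0 + config$couplingA * flux[i])
    sim <- .simulateSeries(config, tauF, seed = config$seed + 97L * i)
    curve <- computeG2(sim$counts, frameInterval = config$frameInterval,
                       q = config$q,
                       meta = list(fluxDensity = flux[i],
                                   truthTau = tauF))
    fit <- fitKWW(curve)
    curves[[i]] <- curve
    fits[[i]] <- fit
  }
  tau <- vapply(fits, function(f) f@tau, numeric(1))
  se <- vapply(fits, function(f) f@se[["tau"]], numeric(1))
  fluxFit <- fitFluxCoupling(flux, tau, se)
  collapse <- rescaleTimeAxis(curves, fluxFit, kwwFits = fits)
  bundle <- list(g2Curves = curves, kwwFits = fits, fluxFit = fluxFit,
                 collapse = collapse,
                 perFlux = data.frame(flux = flux, tau = tau, se = se,
                                      alpha = vapply(fits, function(f)
                                        f@alpha, numeric(1))))
  bundle$manifest <- .manifest(config)
  if (!is.null(outDir)) bundle$files <- .writeFluxBundle(bundle, outDir)
  bundle
}

#' Default temperature-scan configuration
#'
#' Cooling grid 290 -> 180 K (densified near the expected anomaly), flux
#' density 1.5e6 (ph/s)/um^2, Arrhenius ground truth A = 1.8 s,
#' Ea = 9.4 kJ/mol, beam coupling a = 1.1e-8 um^2/ph; analysis at
#' Q = 0.1 1/nm. Intermittency (the heterogeneity schedule) is off by
#' default; pass a \linkS4class{HeterogeneitySchedule} to enable it.
#'
#' @param seed RNG seed
#' @param het optional \linkS4class{HeterogeneitySchedule}
#' @return config list for \code{\link{runTemperatureScan}}
#' @export
temperatureScanConfig <- function(seed = 1, het = NULL) {
  list(
    mode = "simulate",
    temperatures = c(290, 270, 250, 240, 230, 225, 220, 210, 195, 180),
    fluxDensity = 1.5e6, tau0Amplitude = 1.8, activationEnergy = 9.4,
    couplingA = 1.1e-8, q = 0.1, qTargets = 0.1,
    nFrames = 3000, frameInterval = 2, nModes = 4,
    meanCounts = 60, nScatterers = 32, levyIndex = 1.5,
    het = het, computeChi = TRUE, seed = seed)
}

#' Run the temperature-scan analysis end to end
#'
#' Per temperature: render a synthetic frame stack (Arrhenius tau0 plus
#' beam coupling, optional telegraph intermittency), compute g2 at the
#' analysis Q bin and fit the KWW decay; then correct the fitted rates for
#' the known beam contribution (1/tau0 = 1/tau - a F) and fit the Arrhenius
#' law, locate the KWW-exponent minimum, and (optionally) compute the TTC,
#' chi_T and the chi_0(T) peak. A summary table (T, tau, alpha, chi0) and
#' all fits are written to \code{outDir}.
#'
#' @param config list as from \code{\link{temperatureScanConfig}}, or a
#'   path to an equivalent YAML file
#' @param outDir output directory (created); NULL skips file output
#' @return report bundle list: \code{summary} (data.frame), \code{arrhenius}
#'   (\linkS4class{ArrheniusFit}), \code{minimum} (\linkS4class{MinimumFit}),
#'   \code{chi0} (\linkS4class{Chi0Series} or NULL), \code{g2Curves},
#'   \code{kwwFits}, \code{chiCurves}, \code{manifest}, \code{files}
#' @export
runTemperatureScan <- function(config = temperatureScanConfig(),
                               outDir = NULL) {
  config <- .loadConfig(config, temperatureScanConfig())
  if (length(config$temperatures) < 5L)
    stop("config error: need at least 5 temperatures")
  protocol <- TemperatureProtocol(
    temperatures = config$temperatures, fluxDensity = config$fluxDensity,
    tau0Amplitude = config$tau0Amplitude,
    activationEnergy = config$activationEnergy,
    couplingA = config$couplingA)
  base <- SimConfig(
    nScatterers = config$nScatterers, levyIndex = config$levyIndex,
    nModes = config$nModes, meanCounts = config$meanCounts,
    frameInterval = config$frameInterval, nFrames = config$nFrames,
    qTargets = config$qTargets, seed = config$seed)
  stacks <- generateTemperatureScan(protocol, base = base,
                                    het = config$het, qRef = config$q)
  tb <- targetBinEdges(sort(base@qTargets))
  qbin <- tb$bin[which.min(abs(sort(base@qTargets) - config$q))]
  curves <- list(); fits <- list(); chiCurves <- list()
  for (i in seq_along(stacks)) {
    st <- stacks[[i]]
    qmap <- buildQMap(st@geometry, binEdges = st@metadata$binEdges)
    curve <- computeG2(st, qmap, qbin)
    fit <- fitKWW(curve)
    curves[[i]] <- curve
    fits[[i]] <- fit
    if (isTRUE(config$computeChi)) {
      ttc <- computeTTC(st, qmap, qbin)
      beta <- estimateContrast(st, qmap, qbin)
      chiCurves[[i]] <- computeChiT(ttc, beta)
    }
  }
  Tv <- config$temperatures
  tau <- vapply(fits, function(f) f@tau, numeric(1))
  tauSE <- vapply(fits, function(f) f@se[["tau"]], numeric(1))
  alpha <- vapply(fits, function(f) f@alpha, numeric(1))
  alphaSE <- vapply(fits, function(f) f@se[["alpha"]], numeric(1))
  eq <- .beamCorrectRates(tau, tauSE, config$couplingA,
                          config$fluxDensity)
  arrh <- fitArrhenius(Tv[eq$ok], eq$tau0[eq$ok], eq$se[eq$ok])
  minimum <- locateKWWMinimum(Tv, alpha, alphaSE)
  chi0 <- NULL
  chi0Vals <- rep(NA_real_, length(Tv))
  if (isTRUE(config$computeChi)) {
    chi0 <- chi0VsTemperature(Tv, chiCurves)
    chi0Vals <- chi0@chi0
  }
  summary <- data.frame(
    temperature = Tv, tau = tau, tauSE = tauSE, tau0 = eq$tau0,
    alpha = alpha, alphaSE = alphaSE, chi0 = chi0Vals)
  bundle <- list(summary = summary, arrhenius = arrh, minimum = minimum,
                 chi0 = chi0, g2Curves = curves, kwwFits = fits,
                 chiCurves = chiCurves)
  bundle$manifest <- .manifest(config)
  if (!is.null(outDir)) bundle$files <- .writeScanBundle(bundle, outDir)
  bundle
}

# Simulate one flux condition's pixel series with the configured generator.
.simulateSeries <- function(config, tau, seed) {
  if (identical(config$generator, "oracle")) {
    kwwOracleSeries(tau, config$alpha, beta = 1 / config$nModes,
                    nFrames = config$nFrames,
                    frameInterval = config$frameInterval,
                    nPixels = config$nPixels,
                    meanCounts = config$meanCounts, seed = seed)
  } else {
    cfg <- SimConfig(
      nScatterers = config$nScatterers, levyIndex = config$alpha,
      velocityScale = velocityScaleFor(config$q, tau),
      nModes = config$nModes, meanCounts = config$meanCounts,
      frameInterval = config$frameInterval, nFrames = config$nFrames,
      qTargets = config$q, seed = seed)
    simulateBallisticSeries(cfg, config$q, nPixels = config$nPixels)
  }
}

# Invert the known beam contribution: 1/tau0 = 1/tau - a F.
.beamCorrectRates <- function(tau, se, couplingA, fluxDensity) {
  rate0 <- 1 / tau - couplingA * fluxDensity
  ok <- rate0 > 0
  if (any(!ok))
    warning(sum(!ok), " temperature(s) dropped from the Arrhenius fit: ",
            "beam term exceeds the measured rate")
  list(tau0 = ifelse(ok, 1 / rate0, NA_real_),
       se = ifelse(ok, (se / tau^2) / rate0^2, NA_real_), ok = ok)
}

# ------------------------------------------------------------------ config --

.loadConfig <- function(config, defaults) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config error: no such file: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config error: config must be a list")
  cfg <- modifyList(defaults, config)
  cfg
}

# Manifest with everything needed to reproduce deterministic stages.
.manifest <- function(config) {
  cfgSerial <- config
  cfgSerial$het <- if (is.null(config$het)) NULL else
    list(stateRates = config$het@stateRates, fastTau = config$het@fastTau,
         slowTau = config$het@slowTau, Tstar = config$het@Tstar,
         width = config$het@width, maxAmplitude = config$het@maxAmplitude)
  list(package = "xpcsdyn",
       version = as.character(packageVersion("xpcsdyn")),
       rversion = as.character(getRversion()),
       seed = config$seed, config = cfgSerial,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

.writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null",
                       force = TRUE)
  path
}

.kwwAsList <- function(f)
  list(beta = f@beta, baseline = f@baseline, tau = f@tau, alpha = f@alpha,
       se = as.list(f@se), diagnostics = f@diagnostics[
         c("residualNorm", "nPoints", "weighted", "tauAtBound")])

.writeFluxBundle <- function(bundle, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (i in seq_along(bundle$g2Curves)) {
    f <- file.path(outDir, sprintf("g2_flux%02d.csv", i))
    writeG2Csv(bundle$g2Curves[[i]], f)
    files <- c(files, f)
  }
  ff <- bundle$fluxFit
  fits <- file.path(outDir, "flux_fits.json")
  .writeJson(list(
    fluxCoupling = list(tau0 = ff@tau0, a = ff@a, se = as.list(ff@se)),
    perFlux = bundle$perFlux,
    collapseScore = bundle$collapse$score,
    collapsePooledSE = bundle$collapse$pooledSE,
    kww = lapply(bundle$kwwFits, .kwwAsList)), fits)
  manifest <- file.path(outDir, "manifest.json")
  files <- c(files, fits)
  .writeJson(c(bundle$manifest,
               list(outputs = .fileHashes(files))), manifest)
  c(files, manifest)
}

.writeScanBundle <- function(bundle, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  sm <- file.path(outDir, "scan_summary.csv")
  con <- file(sm, "w")
  writeLines(c("# temperature scan summary",
               paste("# columns: temperature_K, tau_s, tauSE_s,",
                     "tau0_equilibrium_s, alpha, alphaSE, chi0")), con)
  write.table(bundle$summary, con, sep = ",", row.names = FALSE,
              quote = FALSE)
  close(con)
  files <- c(files, sm)
  for (i in seq_along(bundle$g2Curves)) {
    f <- file.path(outDir, sprintf("g2_T%03d.csv", i))
    writeG2Csv(bundle$g2Curves[[i]], f)
    files <- c(files, f)
  }
  a <- bundle$arrhenius
  mfit <- bundle$minimum
  res <- list(
    arrhenius = list(A = a@A, Ea = a@Ea, se = as.list(a@se)),
    kwwMinimum = list(Tmin = mfit@Tmin, depth = mfit@depth,
                      width = mfit@width, baseline = mfit@baseline,
                      significant = mfit@significant,
                      method = mfit@method),
    kww = lapply(bundle$kwwFits, .kwwAsList))
  if (!is.null(bundle$chi0)) {
    ch <- bundle$chi0
    res$chi0 <- list(temperatures = ch@temperatures, chi0 = ch@chi0,
                     se = ch@se, dtPeak = ch@dtPeak, Tpeak = ch@Tpeak,
                     TpeakSE = ch@TpeakSE, significant = ch@significant)
  }
  fits <- file.path(outDir, "scan_fits.json")
  .writeJson(res, fits)
  files <- c(files, fits)
  manifest <- file.path(outDir, "manifest.json")
  .writeJson(c(bundle$manifest,
               list(outputs = .fileHashes(files))), manifest)
  c(files, manifest)
}

.fileHashes <- function(files) {
  h <- tools::md5sum(files)
  as.list(setNames(as.character(h), basename(files)))
}
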