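# Detector geometry, Q-mapping, azimuthal averaging and masks.

test_that("Q map reproduces the exact scattering trigonometry", {
  # beamline-scale geometry: 12.4 keV, SDD 21.2 m
  geo <- DetectorGeometry(energyKeV = 12.4, sdd = 21.2, pixelSize = 75,
                          beamCenter = c(10, 10), shape = c(64, 64))
  expect_equal(geo@wavelength, 0.099987252, tolerance = 1e-6)
  # beam-center pixel has Q = 0
  qm <- buildQMap(geo)
  expect_identical(qm@q[11, 11], 0)
  # independent brute-force trigonometry at r = 26.99 mm: the 0.08 1/nm bin
  r <- 26.99e-3
  twoTheta <- atan(r / 21.2)
  expect_equal(twoTheta, 1.27311e-3, tolerance = 1e-5)
  qRef <- 4 * pi / geo@wavelength * sin(twoTheta / 2)
  expect_equal(qOfRadius(r, geo), qRef, tolerance = 1e-12)
  expect_equal(qRef, 0.0800, tolerance = 2e-3)
  # doubling SDD at fixed r halves Q to first order
  geo2 <- DetectorGeometry(energyKeV = 12.4, sdd = 42.4, pixelSize = 75,
                           beamCenter = c(10, 10), shape = c(64, 64))
  expect_equal(qOfRadius(r, geo2) / qOfRadius(r, geo), 0.5,
               tolerance = 1e-5)
  # invalid geometry rejected; beam center outside the detector allowed
  expect_error(DetectorGeometry(energyKeV = 12.4, sdd = -1, pixelSize = 75,
                                beamCenter = c(0, 0), shape = c(8, 8)),
               "positive")
  expect_s4_class(DetectorGeometry(energyKeV = 12.4, sdd = 1,
                                   pixelSize = 75, beamCenter = c(-500, 20),
                                   shape = c(8, 8)), "DetectorGeometry")
})

test_that("bin assignment partitions unmasked pixels and is monotone in r", {
  geo <- testGeometry()
  qm <- buildQMap(geo)
  binned <- !is.na(qm@binIndex)
  # every binned pixel falls inside its half-open interval
  idx <- qm@binIndex[binned]
  qv <- qm@q[binned]
  expect_true(all(qv >= qm@binEdges[idx] & qv < qm@binEdges[idx + 1L]))
  # monotone: larger q never gets a smaller bin
  ord <- order(qv)
  expect_true(all(diff(idx[ord]) >= 0L))
  # each pixel is in at most one bin by construction (single index matrix)
  expect_identical(dim(qm@binIndex), dim(qm@q))
})

test_that("azimuthal average reproduces prescribed radial fields", {
  geo <- testGeometry()
  qm <- buildQMap(geo)
  shape <- geo@shape
  # uniform frames -> profile equals the constant in every populated bin
  st <- constantStack(value = 9L, nFrames = 5L, shape = c(48L, 48L))
  prof <- azimuthalAverage(st, qm)
  expect_true(all(abs(prof@intensity[prof@nPixels > 0] - 9) < 1e-12))
  # power-law field I = I0 (Q/Q0)^-3 -> log-log slope -3
  q0 <- min(qm@q[qm@q > 0])
  field <- ifelse(qm@q > 0, 1e5 * (qm@q / q0)^(-3), 0)
  frames <- array(0L, c(2L, shape))
  frames[1, , ] <- as.integer(round(field))
  frames[2, , ] <- frames[1, , ]
  stPL <- FrameStack(frames, timestamps = 0:1, geometry = geo)
  profPL <- azimuthalAverage(stPL, qm)
  ok <- profPL@nPixels > 30 & is.finite(profPL@intensity) &
    profPL@intensity > 10
  fit <- lm(log(profPL@intensity[ok]) ~ log(profPL@q[ok]))
  expect_equal(unname(coef(fit)[2]), -3, tolerance = 0.05)
  # empty bins are NA, never zero
  edges <- c(qm@binEdges, max(qm@q) * 2, max(qm@q) * 3)
  qm2 <- buildQMap(geo, binEdges = edges)
  prof2 <- azimuthalAverage(st, qm2)
  expect_true(is.na(prof2@intensity[length(prof2@intensity)]))
})

test_that("isotropic input gives consistent azimuthal sector profiles", {
  geo <- testGeometry()
  qm <- buildQMap(geo, binEdges = c(0.04, 0.08, 0.12))
  set.seed(4)
  shape <- geo@shape
  frames <- array(rpois(20 * prod(shape), 50), c(20L, shape))
  st <- FrameStack(frames, timestamps = 0:19, geometry = geo)
  p1 <- azimuthalAverage(st, qm, sector = c(0, 180))
  p2 <- azimuthalAverage(st, qm, sector = c(180, 360))
  for (b in which(p1@nPixels > 50 & p2@nPixels > 50)) {
    pooledSE <- sqrt(50 / (20 * p1@nPixels[b]) + 50 / (20 * p2@nPixels[b]))
    expect_lt(abs(p1@intensity[b] - p2@intensity[b]), 4 * pooledSE)
  }
})

test_that("mask rules are reproducible and exact", {
  st <- constantStack(value = 5L, nFrames = 10L, shape = c(48L, 48L))
  # empty rules -> all-true mask
  expect_true(all(buildMask(st)))
  # a single synthetic hot pixel is masked exactly
  frames <- st@frames
  frames[, 10, 37] <- 5000L
  stHot <- FrameStack(frames, timestamps = st@timestamps,
                      geometry = st@geometry)
  m <- buildMask(stHot, maskRules(hotPixelK = 50))
  expect_false(m[10, 37])
  expect_identical(sum(!m), 1L)
  # angular sector removal matches the analytic annulus area
  ms <- buildMask(st, maskRules(hotPixelK = NULL,
                                sectors = list(c(85, 95))))
  geo <- st@geometry
  rad <- sqrt(outer(((0:47) - 24)^2, ((0:47) - 24)^2, `+`))
  annulus <- rad >= 5 & rad < 20
  removed <- sum(!ms & annulus)
  expected <- (10 / 360) * pi * (20^2 - 5^2)
  expect_lt(abs(removed - expected), 0.25 * expected + 2)
  # over-masking warning names the decimated bin
  qm <- buildQMap(geo, binEdges = c(0.04, 0.08))
  mAll <- matrix(FALSE, 48, 48)
  expect_warning(checkMaskCoverage(qm, mAll), "mask removes")
})
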