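# Dataset container, calibrations, acquisition arithmetic and
# whole-pattern images.

test_that("container round trip is lossless and flags missing calibration", {
  ds <- discStack(ns = 8, nd = 32, poissonSeed = 4)
  path <- file.path(tempdir(), "rt4d")
  saveDataset4D(ds, path)
  ds2 <- loadDataset4D(path)
  expect_identical(counts(ds2), counts(ds))
  expect_equal(scanStep(ds2), scanStep(ds))
  expect_equal(detectorCal(ds2), detectorCal(ds))
  expect_equal(beamCenter(ds2), beamCenter(ds))
  expect_equal(acquisition(ds2)@kV, acquisition(ds)@kV)
  expect_true(ds2@calibrated)

  # strip calibrations from the sidecar: loaded with defaults + flag
  meta <- yaml::read_yaml(file.path(path, "meta.yaml"))
  meta$detector_cal_invA <- NULL
  meta$scan_step_nm <- NULL
  yaml::write_yaml(meta, file.path(path, "meta.yaml"))
  expect_warning(ds3 <- loadDataset4D(path), "uncalibrated")
  expect_equal(detectorCal(ds3), 1.0)
  expect_false(ds3@calibrated)

  expect_error(loadDataset4D(tempfile()), "not a 4D container")
  unlink(path, recursive = TRUE)
})

test_that("generator output keeps its stated scan and detector shape", {
  spec <- simulationSpec(scanShape = c(16L, 16L), detShape = c(33L, 33L),
                         detectorCal = 0.024, seed = 1L)
  sim <- simulateDataset(spec)
  expect_identical(dim(counts(sim$dataset)), c(16L, 16L, 33L, 33L))
  path <- file.path(tempdir(), "shape4d")
  saveDataset4D(sim$dataset, path)
  expect_identical(dim(counts(loadDataset4D(path))), c(16L, 16L, 33L, 33L))
  unlink(path, recursive = TRUE)
})

test_that("binning sums factor^2 blocks, conserves counts and rescales", {
  ds <- discStack(ns = 8, nd = 32, poissonSeed = 7)
  expect_identical(binPatterns(ds, 1), ds)
  expect_error(binPatterns(ds, 0), "positive integer")

  ones <- dataset4D(array(1, c(8, 8, 16, 16)))
  b2 <- binPatterns(ones, 2)
  expect_true(all(counts(b2) == 4))
  expect_equal(detectorCal(b2), 2)

  b <- binPatterns(ds, 2)
  # brute-force block-sum oracle on one pattern
  pat <- counts(ds)[3, 5, , ]
  oracle <- matrix(0, 16, 16)
  for (i in 1:16) for (j in 1:16)
    oracle[i, j] <- sum(pat[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  expect_equal(counts(b)[3, 5, , ], oracle)
  expect_equal(sum(counts(b)[3, 5, , ]), sum(pat))
})

test_that("ADF equals the brute-force annular mask sum exactly", {
  ds <- discStack(ns = 8, nd = 32, poissonSeed = 11)
  rIn <- 0.12; rOut <- 0.25
  adf <- adfImage(ds, rIn, rOut)
  kr <- sedisloc:::.kRadiusGrid(ds)
  mask <- kr >= rIn & kr <= rOut
  oracle <- apply(counts(ds), c(1, 2), function(p) sum(p[mask]))
  expect_identical(adf, oracle)

  # uniform pattern: every ADF pixel = N * v
  u <- dataset4D(array(2, c(8, 8, 32, 32)), detectorCal = 0.012)
  kru <- sedisloc:::.kRadiusGrid(u)
  nAnn <- sum(kru >= 0.12 & kru <= 0.18)
  expect_true(all(adfImage(u, 0.12, 0.18) == 2 * nAnn))

  # a bright pixel inside the inner radius is excluded
  z <- array(0, c(8, 8, 32, 32))
  z[, , 17, 21] <- 1000   # |k| = 4 px * 0.012 = 0.048 < 0.12
  zds <- dataset4D(z, detectorCal = 0.012)
  expect_true(all(adfImage(zds, 0.12, 0.25) == 0))

  expect_warning(adfImage(ds, 0.12, 10), "beyond the detector edge")
})

test_that("mean pattern matches direct averaging and respects masks", {
  ds <- discStack(ns = 8, nd = 32, poissonSeed = 13)
  mp <- meanPattern(ds)
  oracle <- apply(counts(ds), c(3, 4), mean)
  expect_equal(mp, oracle)

  m1 <- matrix(FALSE, 8, 8); m1[2, 3] <- TRUE
  expect_equal(meanPattern(ds, m1), counts(ds)[2, 3, , ])

  m2 <- matrix(FALSE, 8, 8); m2[c(1, 10)] <- TRUE
  expect_equal(meanPattern(ds, m2),
               (counts(ds)[1, 1, , ] + counts(ds)[2, 2, , ]) / 2)

  expect_error(meanPattern(ds, matrix(FALSE, 8, 8)), "empty")
  expect_equal(sqrtDisplay(matrix(c(-1, 4), 1)), matrix(c(0, 2), 1))
})

test_that("acquisition arithmetic reproduces the instrument figures", {
  g300 <- acquisitionGeometry(300, 0.8, current = 1, dwell = 1)
  g200 <- acquisitionGeometry(200, 0.8, current = 1, dwell = 1)
  expect_equal(signif(probeDiameter(g300), 2), 3.0)
  expect_equal(probeDiameter(g200), 3.8, tolerance = 0.02)
  # inverse proportionality in alpha
  expect_equal(probeDiameter(acquisitionGeometry(300, 1.6)),
               probeDiameter(g300) / 2)
  expect_equal(fluencePerScan(g300), 8.8, tolerance = 0.01)
  expect_equal(fluencePerScan(g200), 5.4, tolerance = 0.01)
  expect_equal(fluencePerScan(acquisitionGeometry(300, 0.8, dwell = 2)),
               2 * fluencePerScan(g300))
  expect_equal(signif(discDiameterReciprocal(g300), 1), 0.08)
  expect_equal(discDiameterReciprocal(acquisitionGeometry(300, 0.4)),
               discDiameterReciprocal(g300) / 2)
  expect_equal(electronsPerPattern(g300), 6241.5, tolerance = 1e-4)

  # fluence and probe size are mutually consistent: fluence * area = dose
  area <- pi * (probeDiameter(g300) * 10)^2 / 4
  expect_equal(fluencePerScan(g300) * area, electronsPerPattern(g300),
               tolerance = 1e-9)
})

test_that("centering recovers planted shifts and is idempotent", {
  ds <- discStack(ns = 8, nd = 32,
                  discs = data.frame(kx = 0.25, ky = -0.15),
                  poissonSeed = NULL)
  # already centred: zero shifts, counts unchanged
  cc0 <- centerAndCorrect(ds, referenceDiscRadius = 3)
  expect_lt(max(abs(cc0$calibration@centerShiftMap)), 0.05)
  expect_equal(counts(cc0$dataset), counts(ds))

  # translate every pattern by a known sub-pixel shift
  sh <- c(3.4, -2.1)
  cnt <- counts(ds)
  for (i in 1:8) for (j in 1:8)
    cnt[i, j, , ] <- pmax(sedisloc:::.fourierShift(cnt[i, j, , ],
                                                   sh[1], sh[2]), 0)
  dsSh <- dataset4D(cnt, detectorCal = 0.012)
  cc <- centerAndCorrect(dsSh, referenceDiscRadius = 3)
  expect_lt(max(abs(cc$calibration@centerShiftMap[, , 1] - sh[1])), 0.1)
  expect_lt(max(abs(cc$calibration@centerShiftMap[, , 2] - sh[2])), 0.1)

  # idempotence: re-centering moves things by < 0.05 px
  cc2 <- centerAndCorrect(cc$dataset, referenceDiscRadius = 3)
  expect_lt(max(abs(cc2$calibration@centerShiftMap)), 0.05)
})

test_that("the affine correction undoes an elliptical distortion", {
  nd <- 64
  bc <- c((nd + 1) / 2, (nd + 1) / 2)
  # ring of radius 12 px, stretched by diag(1.1, 1) in (row, col)
  A <- diag(c(1.1, 1))
  rr <- outer(seq_len(nd) - bc[1], rep(1, nd))
  cc <- outer(rep(1, nd), seq_len(nd) - bc[2])
  # distorted ring: points where |A^{-1} x| = 12
  d <- sqrt((rr / 1.1)^2 + cc^2)
  ring <- exp(-(d - 12)^2 / 2)
  corrected <- sedisloc:::.affineResample(ring, A, bc)
  # radial profile of the corrected ring: centroid radius per azimuth
  az <- seq(0, 2 * pi, length.out = 73)[-73]
  rad <- sapply(az, function(a) {
    t <- seq(8, 16, by = 0.1)
    v <- sedisloc:::.bilinear(corrected, bc[1] + t * sin(a), bc[2] + t * cos(a))
    sum(t * v) / sum(v)
  })
  expect_lt(sd(rad), 0.2)
})
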