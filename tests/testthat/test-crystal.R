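# Unit-cell arithmetic, zone-axis geometry, indexing assistance and
# dislocation-density bookkeeping.

test_that("d-spacings match the published benchmark values", {
  pter <- builtinCell("p-terphenyl")
  expect_equal(round(dSpacing(pter, c(2, 1, 0)), 2), 3.28)
  expect_equal(round(dSpacing(pter, c(2, 0, 0)), 2), 4.05)
  expect_equal(dSpacing(unitCell(1, 1, 1), c(1, 0, 0)), 1.0)
  expect_error(dSpacing(pter, c(0, 0, 0)), "0,0,0")
})

test_that("the reciprocal metric agrees with the orthorhombic closed form", {
  cell <- unitCell(5.2, 7.9, 11.3)
  for (hkl in list(c(1, 0, 0), c(0, 2, 0), c(1, 1, 1), c(3, 1, 2))) {
    dref <- 1 / sqrt(hkl[1]^2 / 5.2^2 + hkl[2]^2 / 7.9^2 + hkl[3]^2 / 11.3^2)
    expect_equal(dSpacing(cell, hkl), dref, tolerance = 1e-12)
  }
})

test_that("zone lists satisfy the zone law and match brute force", {
  cub <- unitCell(1, 1, 1)
  zl <- zoneGList(cub, c(0, 0, 1), 1.1)
  expect_setequal(
    apply(zl[, c("h", "k", "l")], 1, paste, collapse = ","),
    c("1,0,0", "-1,0,0", "0,1,0", "0,-1,0"))
  # right angles between (100) and (010)
  g100 <- zl[zl$h == 1 & zl$k == 0, ]
  g010 <- zl[zl$h == 0 & zl$k == 1, ]
  expect_equal(abs(sedisloc:::.angDiff180(g100$phi, g010$phi)), 90,
               tolerance = 1e-9)

  mono <- builtinCell("anthracene")
  zone <- c(1, 0, 1)
  zl2 <- zoneGList(mono, zone, 0.7)
  expect_true(all(zl2$h * zone[1] + zl2$k * zone[2] + zl2$l * zone[3] == 0))
  expect_equal(zl2$magnitude,
               1 / vapply(seq_len(nrow(zl2)), function(i)
                 dSpacing(mono, as.numeric(zl2[i, c("h", "k", "l")])), 0))
  # brute-force enumeration oracle over |h|,|k|,|l| <= 10
  idx <- as.matrix(expand.grid(h = -10:10, k = -10:10, l = -10:10))
  idx <- idx[rowSums(abs(idx)) > 0 & idx %*% zone == 0, , drop = FALSE]
  Ms <- sedisloc:::.reciprocalBasis(mono)
  gm <- sqrt(rowSums((idx %*% Ms)^2))
  oracle <- idx[gm <= 0.7, , drop = FALSE]
  expect_setequal(apply(zl2[, c("h", "k", "l")], 1, paste, collapse = ","),
                  apply(oracle, 1, paste, collapse = ","))
})

test_that("direction projection shares the zone-plane basis with g lists", {
  ortho <- unitCell(5, 7, 9)
  azB <- projectDirection(ortho, c(0, 0, 1), c(0, 1, 0))
  azA <- projectDirection(ortho, c(0, 0, 1), c(1, 0, 0))
  expect_equal(abs(sedisloc:::.angDiff180(azB, azA)), 90, tolerance = 1e-9)
  expect_error(projectDirection(ortho, c(0, 0, 1), c(0, 0, 2)),
               "undefined projection")

  # numeric 3D projection oracle on a monoclinic cell
  mono <- builtinCell("p-terphenyl")
  zone <- c(0, 0, 1)
  zb <- sedisloc:::.zoneBasis(mono, zone)
  for (uvw in list(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(2, -1, 1))) {
    t3 <- as.numeric(uvw %*% sedisloc:::.directBasis(mono))
    tp <- t3 - sum(t3 * zb$n) * zb$n
    oracle <- (atan2(sum(tp * zb$e2), sum(tp * zb$e1)) * 180 / pi) %% 360
    expect_equal(projectDirection(mono, zone, uvw), oracle,
                 tolerance = 1e-9)
  }
  # in-zone g azimuths and the dual real-space azimuths live in one frame:
  # for the orthorhombic cell the [100] direction is parallel to g(100)
  zl <- zoneGList(ortho, c(0, 0, 1), 0.3)
  gphi <- zl$phi[zl$h == 1 & zl$k == 0]
  expect_equal(sedisloc:::.acuteAngle(gphi, azA), 0, tolerance = 1e-9)
})

test_that("Burgers matching ranks candidates and flags misses", {
  ortho <- unitCell(5, 7, 9)
  azB <- projectDirection(ortho, c(0, 0, 1), c(0, 1, 0))
  m <- matchBurgers(azB + 1, ortho, c(0, 0, 1))
  expect_identical(as.integer(m[1, c("u", "v", "w")]), c(0L, 1L, 0L))
  expect_lt(m$mismatch[1], 1.5)
  expect_true(attr(m, "matched"))
  # adding 180 degrees leaves the ranking unchanged
  m2 <- matchBurgers(azB + 1 + 180, ortho, c(0, 0, 1))
  expect_identical(m2[, c("u", "v", "w")], m[, c("u", "v", "w")])
  # an azimuth far from every candidate is unmatched but ranked
  bad <- matchBurgers(azB + 1, ortho, c(0, 0, 1),
                      candidates = rbind(c(1, 0, 0)), tol = 3)
  expect_false(attr(bad, "matched"))
  expect_equal(nrow(bad), 1)
})

test_that("indexing assistance identifies the zone from geometry alone", {
  mono <- builtinCell("p-terphenyl")
  zones <- list(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0), c(1, 0, 1))
  mkObs <- function(zone, rot, cell = mono, gmax = 0.45) {
    zl <- zoneGList(cell, zone, gmax)
    lapply(seq_len(nrow(zl)), function(i)
      gVector(zl$magnitude[i] * cos((zl$phi[i] + rot) * pi / 180),
              zl$magnitude[i] * sin((zl$phi[i] + rot) * pi / 180)))
  }
  r <- indexAssist(mkObs(c(0, 0, 1), 0), mono, zones)
  expect_identical(as.integer(r[1, c("u", "v", "w")]), c(0L, 0L, 1L))
  expect_true(attr(r, "indexed"))
  asg <- attr(r, "assignments")
  expect_true(all(asg$h * 0 + asg$k * 0 + asg$l * 1 == 0))
  # rotation invariance
  r25 <- indexAssist(mkObs(c(0, 0, 1), 25), mono, zones)
  expect_identical(as.integer(r25[1, c("u", "v", "w")]), c(0L, 0L, 1L))
  # negative control: a foreign cell's pattern stays unindexed
  foreign <- unitCell(23.1, 17.3, 19.7, beta = 113)
  rNeg <- indexAssist(mkObs(c(0, 0, 1), 0, cell = foreign, gmax = 0.3),
                      mono, zones)
  expect_false(attr(rNeg, "indexed"))
})

test_that("dislocation density follows length over probed volume", {
  l10 <- dislocationLine(rbind(c(0, 0), c(10000, 0)))   # 10 um
  rho <- dislocationDensity(list(l10), area = 25, thickness = c(100, 100))
  expect_equal(unname(rho["low"]), 4e8, tolerance = 1e-12)
  # thickness bounds 10 and 100 nm: exactly a 10x density ratio
  rng <- dislocationDensity(list(l10), area = 25, thickness = c(10, 100))
  expect_equal(unname(rng["high"] / rng["low"]), 10, tolerance = 1e-12)
  expect_equal(unname(dislocationDensity(list(), 25, c(10, 100))["low"]), 0)
})

test_that("the out-of-plane bound reproduces the thin-film geometry", {
  expect_lt(outOfPlaneBound(2, 100), 3)
  expect_equal(outOfPlaneBound(2, 100), atan2(100, 2000) * 180 / pi)
  expect_equal(outOfPlaneBound(2, 0), 0)
  expect_equal(outOfPlaneBound(2, 10), 0.2865, tolerance = 1e-3)
})

test_that("CIF cell constants round-trip through the minimal reader", {
  cif <- file.path(tempdir(), "cell.cif")
  writeLines(c("data_test",
               "_cell_length_a   8.106(2)",
               "_cell_length_b   5.613(1)",
               "_cell_length_c   13.613(3)",
               "_cell_angle_alpha 90",
               "_cell_angle_beta  92.02(1)",
               "_cell_angle_gamma 90",
               "loop_", "_atom_site_label"), cif)
  cell <- readCellCIF(cif)
  expect_equal(cell@a, 8.106)
  expect_equal(cell@beta, 92.02)
  expect_equal(round(dSpacing(cell, c(2, 1, 0)), 2), 3.28)
  unlink(cif)
})
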