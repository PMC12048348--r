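# Bragg-disc detection, sub-pixel refinement, g-vector consolidation and
# virtual dark-field reconstruction.

test_that("disc finding recovers planted discs and honours exclusions", {
  expect_equal(nrow(findDiscs(matrix(0, 64, 64))), 0)
  expect_error(findDiscs(matrix(1, 16, 16), sigmaLow = 3, sigmaHigh = 2),
               "sigmaLow")

  # six Gaussian discs of the width set by the 0.08 1/Angstrom diameter
  set.seed(3)
  truth <- cbind(row = c(12, 20, 40, 50, 28, 44),
                 col = c(40, 14, 52, 20, 55, 12))
  pat <- matrix(0, 64, 64)
  for (i in 1:6)
    pat <- pat + 100 * exp(-outer((1:64 - truth[i, 1])^2,
                                  (1:64 - truth[i, 2])^2, "+") / (2 * 1.7^2))
  found <- findDiscs(pat)
  expect_equal(nrow(found), 6)
  for (i in 1:6) {
    d <- sqrt((found$row - truth[i, 1])^2 + (found$col - truth[i, 2])^2)
    expect_lt(min(d), 1)
  }

  # direct beam only + exclusion zone: nothing survives
  beam <- 1000 * exp(-outer((1:64 - 32.5)^2, (1:64 - 32.5)^2, "+") / (2 * 2^2))
  expect_equal(nrow(findDiscs(beam, excludeCenter = 0.1 / 0.012)), 0)
})

test_that("centre-of-mass refinement reaches sub-pixel accuracy", {
  mk <- function(r, c) 100 * exp(-outer((1:32 - r)^2, (1:32 - c)^2, "+") /
                                   (2 * 1.7^2))
  # symmetric disc on a pixel: recovered exactly
  expect_equal(refineCOM(mk(16, 20), c(16, 20), window = 4), c(16, 20),
               tolerance = 1e-6)
  # planted sub-pixel offset
  pos <- refineCOM(mk(16.3, 19.7), c(16, 20), window = 4)
  expect_lt(sqrt(sum((pos - c(16.3, 19.7))^2)), 0.05)
  # flat window: undefined centroid
  expect_error(refineCOM(matrix(5, 32, 32), c(16, 16), window = 3),
               "refinement error")
  expect_error(refineCOM(mk(16, 16), c(2, 2), window = 4), "window")
})

test_that("detection plus refinement is accurate across noise realizations", {
  truth <- cbind(row = c(10, 24, 38, 52), col = c(40, 12, 52, 24))
  base <- matrix(0, 64, 64)
  for (i in 1:4)
    base <- base + 60 * exp(-outer((1:64 - truth[i, 1])^2,
                                   (1:64 - truth[i, 2])^2, "+") / (2 * 1.7^2))
  errs <- unlist(lapply(1:100, function(sd) {
    set.seed(sd)
    pat <- matrix(rpois(length(base), base), 64, 64)
    found <- findDiscs(pat, threshold = 0.3)
    sapply(seq_len(nrow(truth)), function(i) {
      d2 <- (found$row - truth[i, 1])^2 + (found$col - truth[i, 2])^2
      j <- which.min(d2)
      if (sqrt(d2[j]) > 3) return(NA_real_)
      pos <- refineCOM(pat, c(found$row[j], found$col[j]), window = 3)
      sqrt(sum((pos - truth[i, ])^2))
    })
  }))
  expect_lt(mean(is.na(errs)), 0.02)
  expect_lt(sqrt(mean(errs^2, na.rm = TRUE)), 0.1)
})

test_that("g-vector azimuths are antisymmetric and rotation-equivariant", {
  g <- gVector(0.2, 0.1)
  gm <- gVector(-0.2, -0.1)
  expect_equal((gm@phi - g@phi) %% 360, 180)
  g90 <- gVector(0.2, 0.1, rotationOffset = 90)
  expect_equal((g90@phi - g@phi) %% 360, 90)
  expect_equal(g90@magnitude, g@magnitude)
  expect_equal(g@magnitude, sqrt(0.2^2 + 0.1^2))
})

test_that("consolidation recovers the planted reflection list", {
  spec <- simulationSpec(seed = 21L, phaseC = 60)
  sim <- simulateDataset(spec)
  gv <- consolidateGVectors(sim$dataset, seed = 5L)
  expect_equal(length(gv), nrow(sim$truth@table))
  tab <- gVectorTable(gv)
  for (i in seq_len(nrow(sim$truth@table))) {
    d <- sqrt((tab$kx - sim$truth@table$kx[i])^2 +
                (tab$ky - sim$truth@table$ky[i])^2)
    expect_lt(min(d), 0.02)
  }
  # Friedel pairs linked
  fr <- attr(gv, "friedel")
  expect_true(all(!is.na(fr)))
  for (i in seq_along(gv))
    expect_lt(sqrt(sum((gv[[i]]@k + gv[[fr[i]]]@k)^2)), 0.04)

  # re-seeding at a larger sample fraction reproduces the same clusters
  gv2 <- consolidateGVectors(sim$dataset, sampleFraction = 0.1, seed = 99L)
  expect_equal(length(gv2), length(gv))
  tab2 <- gVectorTable(gv2)
  for (i in seq_len(nrow(tab)))
    expect_lt(min(sqrt((tab2$kx - tab$kx[i])^2 + (tab2$ky - tab$ky[i])^2)),
              0.02)
})

test_that("VDF equals the brute-force aperture sum exactly", {
  ds <- discStack(ns = 8, nd = 32, poissonSeed = 17)
  g <- gVector(0.2, 0.1)
  v <- vdf(ds, g, apertureRadius = 0.024)
  pos <- sedisloc:::.gToPixel(ds, g)
  rr <- outer((1:32 - pos[1])^2, (1:32 - pos[2])^2, "+")
  mask <- rr <= (0.024 / 0.012)^2
  oracle <- apply(counts(ds), c(1, 2), function(p) sum(p[mask]))
  expect_identical(v@image, oracle)

  # an aperture on an empty detector region integrates to ~nothing
  vEmpty <- vdf(ds, gVector(-0.05, 0.15), apertureRadius = 0.02)
  expect_true(all(vEmpty@image < 5))

  expect_error(vdf(ds, gVector(0.01, 0), apertureRadius = 0.02),
               "direct beam")
  expect_warning(vdf(ds, g, apertureRadius = 0.06), "overlap")
})

test_that("VDFs over a disjoint aperture tiling never exceed total counts", {
  ds <- discStack(ns = 8, nd = 32, poissonSeed = 23)
  centersK <- expand.grid(kx = c(-0.1, 0.1), ky = c(-0.1, 0.1))
  tot <- matrix(0, 8, 8)
  for (i in seq_len(nrow(centersK)))
    tot <- tot + vdf(ds, gVector(centersK$kx[i], centersK$ky[i]),
                     apertureRadius = 0.02)@image
  full <- apply(counts(ds), c(1, 2), sum)
  expect_true(all(tot <= full))
})

test_that("VDF usability separates contoured reflections from background", {
  sc <- contourScene(f = 0, noiseSeed = 2)
  expect_true(vdfUsable(sc$vdf))
  flat <- methods::new("VDFImage",
                       image = matrix(rpois(4096, 2), 64, 64),
                       g = gVector(0.2, 0.1), apertureRadius = 0.02,
                       scanStep = 8)
  expect_false(vdfUsable(flat))
})
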