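# Azimuthal displacement model, its fit, and the derived Burgers-vector
# quantities (azimuth, invisibility, character, handedness, slip system).

test_that("the displacement model obeys its closed forms and symmetry", {
  expect_equal(modelF(40, 10, 1, 40), 10 * pi / 4)
  expect_equal(modelF(130, 10, 1, 40), 0, tolerance = 1e-12)
  expect_equal(modelF(c(40, 220), 10, 1, 40), rep(10 * pi / 4, 2))
  # even symmetry about C and 180-degree period
  phi0 <- c(5, 17, 33, 61, 89)
  expect_equal(modelF(40 + phi0, 12, 2.5, 40), modelF(40 - phi0, 12, 2.5, 40))
  expect_equal(modelF(phi0, 12, 2.5, 40), modelF(phi0 + 180, 12, 2.5, 40))
  # the maximum sits at C
  phi <- seq(0, 179.5, by = 0.5)
  expect_equal(phi[which.max(modelF(phi, 8, 3, 72))], 72)
})

test_that("noise-free profiles are recovered to machine-level precision", {
  phi <- seq(7, 337, by = 30)
  truth <- c(A = 12, B = 2.5, C = 40)
  pr <- profileFrom(phi, modelF(phi, 12, 2.5, 40), rep(0.3, length(phi)))
  ft <- fitDisplacementModel(pr)
  expect_equal(unname(fitCoefficients(ft)), unname(truth), tolerance = 1e-6)
  expect_lt(ft@rms, 1e-6)
  # profile-likelihood intervals exist and bracket the estimates
  ci <- confint95(ft)
  expect_true(all(ci[, 1] <= fitCoefficients(ft) + 1e-9))
  expect_true(all(ci[, 2] >= fitCoefficients(ft) - 1e-9))
})

test_that("noisy fits recover the phase and cover the truth", {
  set.seed(42)
  hits <- 0L; errs <- numeric(40)
  for (r in 1:40) {
    C <- runif(1, 0, 180)
    pr <- noisyProfile(12, 2.5, C, n = 16, noise = 0.05, seed = 1000 + r)
    ft <- fitDisplacementModel(pr)
    errs[r] <- abs(((C - ft@phaseC + 90) %% 180) - 90)
    ci <- confint95(ft)["C", ]
    d <- ((C - ft@phaseC + 90) %% 180) - 90
    hits <- hits + (ci[1] - ft@phaseC <= d && d <= ci[2] - ft@phaseC)
  }
  expect_lt(median(errs), 2)
  expect_gte(hits / 40, 0.8)
})

test_that("fit refusals and the degenerate zero profile behave as stated", {
  phi <- c(10, 50, 90)
  expect_error(fitDisplacementModel(
    profileFrom(phi, c(1, 2, 3), rep(0.3, 3))), "fewer than 4")
  phiNarrow <- c(10, 20, 30, 40)
  expect_error(fitDisplacementModel(
    profileFrom(phiNarrow, 1:4, rep(0.3, 4))), "span")

  phiW <- seq(10, 340, by = 30)
  prZero <- profileFrom(phiW, rnorm(length(phiW), 0, 0.1),
                        rep(0.5, length(phiW)))
  ftZ <- fitDisplacementModel(prZero)
  expect_true(ftZ@noDistortion)
  expect_equal(ftZ@ampA, 0)
  expect_true(is.na(ftZ@phaseC))
  expect_true(is.na(burgersAzimuth(ftZ)))
})

test_that("rotating every azimuth shifts the phase and nothing else", {
  phi <- seq(3, 333, by = 30)
  pr0 <- profileFrom(phi, modelF(phi, 9, 1.8, 25), rep(0.2, length(phi)))
  ft0 <- fitDisplacementModel(pr0)
  for (delta in c(35, 90, 140)) {
    phiR <- (phi + delta) %% 360
    prR <- profileFrom(phiR, modelF(phi, 9, 1.8, 25), rep(0.2, length(phi)))
    ftR <- fitDisplacementModel(prR)
    expect_equal(ftR@ampA, ft0@ampA, tolerance = 1e-7)
    expect_equal(ftR@shapeB, ft0@shapeB, tolerance = 1e-6)
    expect_angle_close(ftR@phaseC, ft0@phaseC + delta, 1e-5)
  }
})

test_that("the Burgers azimuth applies the rotation offset modulo 180", {
  mkFit <- function(C) {
    phi <- seq(3, 333, by = 30)
    fitDisplacementModel(profileFrom(phi, modelF(phi, 10, 2, C),
                                     rep(0.2, length(phi))))
  }
  expect_equal(as.numeric(burgersAzimuth(mkFit(40))), 40, tolerance = 1e-5)
  expect_equal(as.numeric(burgersAzimuth(mkFit(170), rotationOffset = 20)),
               10, tolerance = 1e-4)
})

test_that("the invisibility set collects zero-displacement g near C+90", {
  C <- 40
  phi <- c(40, 75, 110, 130, 145, 220, 310, 350)
  d <- modelF(phi, 10, 2, C)
  sig <- rep(0.4, length(phi))
  pr <- profileFrom(phi, d, sig)
  ft <- fitDisplacementModel(pr)
  inv <- invisibilitySet(pr, ft)
  invPhi <- vapply(inv, function(g) g@phi, 0)
  expect_true(130 %in% round(invPhi))      # at C + 90: in the set
  expect_true(310 %in% round(invPhi))      # antipode of C + 90
  expect_false(40 %in% round(invPhi))      # at C: certainly not
  expect_false(220 %in% round(invPhi))
  # zeroTol = 0 keeps only exact zeros
  inv0 <- invisibilitySet(pr, ft, zeroTol = 0)
  expect_true(all(round(vapply(inv0, function(g) g@phi, 0)) %in% c(130, 310)))
  # no usable g near C +/- 90 at all -> empty with a note
  phi2 <- c(20, 40, 60, 80, 200, 220, 240, 260)
  pr2 <- profileFrom(phi2, modelF(phi2, 10, 2, C), rep(0.4, 8))
  ft2 <- fitDisplacementModel(pr2)
  inv2 <- invisibilitySet(pr2, ft2, angleTol = 10)
  expect_length(inv2, 0)
  expect_equal(attr(inv2, "note"), "unconstrained invisibility")
})

test_that("character classification follows the B-to-u angle", {
  line <- dislocationLineAt(c(0, 0), 30, 100)
  expect_equal(classifyCharacter(30, line)@label, "screw")
  expect_equal(classifyCharacter(120, line)@label, "edge")
  expect_equal(classifyCharacter(75, line)@label, "mixed")
  expect_equal(classifyCharacter(75, line)@angleBu, 45)
  expect_equal(classifyCharacter(NA, line)@label, "undetermined")
  # symmetric under 180-degree flips of either azimuth
  expect_equal(classifyCharacter(30 + 180, line)@label, "screw")
  lineFlip <- dislocationLineAt(c(0, 0), 210, 100)
  expect_equal(classifyCharacter(30, lineFlip)@label, "screw")
  # edge component azimuth is perpendicular to u, on B's side
  cc <- classifyCharacter(75, line)
  expect_equal(cc@edgeComponentAzimuth, 120)
  # per-segment calls for a curved line
  curved <- dislocationLine(rbind(c(0, 0), c(100, 0), c(170, -70)))
  seg <- attr(classifyCharacter(0, curved), "segments")
  expect_equal(seg$label, c("screw", "mixed"))
})

test_that("g.B integers reproduce the invisibility bookkeeping", {
  expect_identical(gbInteger(c(2, 1, 0), c(0, 1, 0)), 1L)
  expect_identical(gbInteger(c(2, 0, 0), c(0, 1, 0)), 0L)
  expect_identical(gbInteger(c(1, 4, 1), c(1, 0, 2)), 3L)
  expect_identical(gbInteger(c(-2, 0, 0), c(0, 1, 0)), 0L)
})

test_that("screw handedness reads the planted contour twist and parity", {
  mkPair <- function(hand, seed = 61) {
    spec <- simulationSpec(seed = seed, phaseC = 30, handedness = hand)
    sim <- simulateDataset(spec)
    gv <- consolidateGVectors(sim$dataset, seed = 2L)
    uAz <- lineAzimuth(spec@line)
    near <- which(vapply(gv, function(g)
      sedisloc:::.acuteAngle(g@phi, uAz) <= 20, TRUE))
    list(vdfs = lapply(gv[near[1:2]], function(g) vdf(sim$dataset, g, 0.02)),
         line = spec@line)
  }
  pr <- mkPair(1)
  expect_equal(as.character(screwHandedness(pr$vdfs, pr$line)), "right")
  pl <- mkPair(-1, seed = 62)
  expect_equal(as.character(screwHandedness(pl$vdfs, pl$line)), "left")
  # zero twist -> undetermined
  p0 <- mkPair(0, seed = 63)
  expect_equal(as.character(screwHandedness(p0$vdfs, p0$line)),
               "undetermined")
  # mirror parity: reflecting the images about the axis perpendicular to
  # the (horizontal, centred) line keeps each side's content on its side
  # but reverses every azimuth, so the twist sense and the call flip
  lineH <- dislocationLineAt(c(252, 252), 0, 280)   # between pixel rows
  specH <- simulationSpec(seed = 64, phaseC = 0, handedness = 1,
                          line = lineH)
  simH <- simulateDataset(specH)
  gvH <- consolidateGVectors(simH$dataset, seed = 2L)
  nearH <- which(vapply(gvH, function(g)
    sedisloc:::.acuteAngle(g@phi, 0) <= 20, TRUE))
  vdfsH <- lapply(gvH[nearH[1:2]], function(g) vdf(simH$dataset, g, 0.02))
  expect_equal(as.character(screwHandedness(vdfsH, lineH)), "right")
  flip <- function(v) { v@image <- v@image[, rev(seq_len(ncol(v@image)))]; v }
  expect_equal(as.character(screwHandedness(lapply(vdfsH, flip), lineH)),
               "left")
  # a g far from the line direction violates the precondition
  spec <- simulationSpec(seed = 65, phaseC = 30, handedness = 1)
  sim <- simulateDataset(spec)
  gv <- consolidateGVectors(sim$dataset, seed = 2L)
  far <- which(vapply(gv, function(g)
    sedisloc:::.acuteAngle(g@phi, lineAzimuth(spec@line)) > 40, TRUE))
  expect_error(screwHandedness(lapply(gv[far[1:2]], function(g)
    vdf(sim$dataset, g, 0.02)), spec@line), "precondition")
})

test_that("slip systems combine B and the projected line direction", {
  # monoclinic cell, [001] zone, b = [010], u in the a-b plane
  cell <- builtinCell("p-terphenyl")
  uAzProj <- projectDirection(cell, c(0, 0, 1), c(1, 0, 0))
  line <- dislocationLineAt(c(0, 0), uAzProj, 100)
  out <- assignSlipSystem(c(0, 1, 0), line, c(0, 0, 1), cell)
  expect_identical(out$plane, c(0L, 0L, 1L))
  expect_match(out$label, "\\[010\\]\\(001\\)")
  # pure screw: plane undetermined
  lineB <- dislocationLineAt(c(0, 0),
                             projectDirection(cell, c(0, 0, 1), c(0, 1, 0)),
                             100)
  outS <- assignSlipSystem(c(0, 1, 0), lineB, c(0, 0, 1), cell)
  expect_match(outS$label, "undetermined")
  # orthorhombic fixture with a planted (b, plane)
  ortho <- unitCell(5, 7, 9)
  uAz2 <- projectDirection(ortho, c(0, 0, 1), c(1, 0, 0))
  line2 <- dislocationLineAt(c(0, 0), uAz2, 100)
  out2 <- assignSlipSystem(c(0, 1, 0), line2, c(0, 0, 1), ortho)
  expect_identical(out2$plane, c(0L, 0L, 1L))
})
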