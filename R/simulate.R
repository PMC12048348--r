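# Ground-truthed synthetic SED scenes: a thin, cylindrically bent crystal
# (one straight bend contour per reflection, all sharing the bend-gradient
# direction) crossed by a straight in-plane dislocation that displaces
# each contour along the line according to the azimuthal displacement
# model, with Poisson counting noise at a stated dose.

#' Straight dislocation line by centre, azimuth and length
#'
#' @param center (x, y) centre in nm.
#' @param azimuth line azimuth in degrees (y-up).
#' @param length line length in nm.
#' @param positiveSense +1 or -1.
#' @return a [DislocationLine-class].
#' @export
dislocationLineAt <- function(center, azimuth, length, positiveSense = 1) {
  d <- .dirVec(azimuth)
  dislocationLine(rbind(center - d * length / 2, center + d * length / 2),
                  positiveSense = positiveSense)
}

#' Reflection table at chosen azimuths
#'
#' @param phis azimuths in degrees (scan frame, y-up).
#' @param mags |g| values in inverse Angstrom (recycled).
#' @return data.frame with kx, ky columns for [simulationSpec()].
#' @export
reflectionsAt <- function(phis, mags) {
  mags <- rep_len(mags, length(phis))
  data.frame(kx = mags * cos(.deg2rad(phis)),
             ky = mags * sin(.deg2rad(phis)))
}

#' Default reflection set: five Friedel pairs
#'
#' Ten reflections at azimuths `phaseC + (0, 36, ..., 324)` degrees with
#' pairwise-distinct magnitudes shared within each +g/-g pair, emulating a
#' low-index zone-axis pattern.
#'
#' @param phaseC planted Burgers azimuth, degrees.
#' @param mags five magnitudes in inverse Angstrom.
#' @return data.frame with kx, ky.
#' @export
defaultReflections <- function(phaseC,
                               mags = seq(0.20, 0.32, length.out = 5)) {
  reflectionsAt(.wrap360(phaseC + seq(0, 324, by = 36)), rep(mags, 2))
}

#' Construct a synthetic scene specification
#'
#' Defaults follow the acquisition described for low-dose SED of molecular
#' crystals: 300 kV, 0.8 mrad, 1 pA x 1 ms (about 6.2e3 electrons per
#' pattern), a 64 x 64 probe raster at 8 nm per pixel, a bend radius of a
#' few micrometres giving one contour of a few scan pixels' width per
#' reflection, and a planted displacement model of amplitude ~3 scan
#' pixels.
#'
#' @param scanShape integer (rows, cols).
#' @param scanStep nm per scan pixel.
#' @param detShape integer detector (rows, cols).
#' @param detectorCal inverse Angstrom per detector pixel.
#' @param geometry an [AcquisitionGeometry-class].
#' @param reflections data.frame with kx, ky (and optional h, k, l);
#'   default [defaultReflections()] at `phaseC`.
#' @param curvatureRadius effective bending radius, micrometres.
#' @param rockingSigma rocking-curve width, inverse Angstrom.
#' @param diffractedFraction peak diffracted intensity fraction per disc.
#' @param line a [DislocationLine-class]; default a straight line of 0.55
#'   field-of-view length at 30 degrees through the field centre.
#' @param ampA,shapeB,phaseC planted model parameters.
#' @param handedness -1, 0 or +1.
#' @param twistDeg planted contour twist for reflections near the line.
#' @param bendAzimuth contour-normal azimuth; defaults to the line azimuth
#'   (contours crossing the line at right angles).
#' @param artifactRow onset row of a uniform mid-scan jump (`NA` = none).
#' @param artifactJumpPx jump amplitude along the bend normal, scan px.
#' @param dose expected electrons per pattern; defaults to
#'   current x dwell / e from `geometry`.
#' @param rotationOffset scan-to-detector rotation offset, degrees.
#' @param seed integer RNG seed.
#' @return a [SimulationSpec-class].
#' @export
simulationSpec <- function(scanShape = c(64L, 64L), scanStep = 8,
                           detShape = c(64L, 64L), detectorCal = 0.012,
                           geometry = acquisitionGeometry(),
                           reflections = NULL, curvatureRadius = 5,
                           rockingSigma = 0.001, diffractedFraction = 0.03,
                           line = NULL, ampA = 24, shapeB = 2, phaseC = 60,
                           handedness = 0, twistDeg = 8, bendAzimuth = NULL,
                           artifactRow = NA_real_, artifactJumpPx = 3,
                           dose = NULL, rotationOffset = 0, seed = 1L) {
  scanShape <- as.integer(scanShape); detShape <- as.integer(detShape)
  fov <- (scanShape - 1L) * scanStep            # (rows, cols) extent, nm
  if (is.null(line))
    line <- dislocationLineAt(c(fov[2] / 2, fov[1] * 0.45), 30,
                              0.55 * min(fov))
  if (is.null(reflections)) reflections <- defaultReflections(phaseC)
  if (is.null(bendAzimuth)) bendAzimuth <- lineAzimuth(line)
  if (is.null(dose)) dose <- geometry@current * 1e-12 * geometry@dwell *
      1e-3 / 1.602176634e-19
  spec <- methods::new("SimulationSpec", scanShape = scanShape,
    scanStep = scanStep, detShape = detShape, detectorCal = detectorCal,
    geometry = geometry, reflections = reflections,
    curvatureRadius = curvatureRadius, rockingSigma = rockingSigma,
    diffractedFraction = diffractedFraction, line = line, ampA = ampA,
    shapeB = shapeB, phaseC = phaseC, handedness = handedness,
    twistDeg = twistDeg, bendAzimuth = bendAzimuth,
    artifactRow = artifactRow, artifactJumpPx = artifactJumpPx,
    dose = dose, rotationOffset = rotationOffset, seed = as.integer(seed))
  # reflections must not overlap within one disc diameter
  k <- as.matrix(spec@reflections[, c("kx", "ky")])
  if (nrow(k) > 1) {
    dd <- as.matrix(stats::dist(k))
    diag(dd) <- Inf
    if (min(dd) < discDiameterReciprocal(spec@geometry))
      stop("spec error: reflections overlap within one disc diameter")
  }
  spec
}

#' Expected electrons per pattern of a scene
#'
#' The dose the generator scales each pattern's expectation to;
#' current x dwell / e (about 6.24e3 for 1 pA, 1 ms) unless overridden.
#'
#' @param spec a [SimulationSpec-class].
#' @return expected electrons per pattern.
#' @export
expectedCounts <- function(spec) {
  stopifnot(is(spec, "SimulationSpec"))
  spec@dose
}

#' Simulate a ground-truthed 4D dataset
#'
#' For each reflection g a straight bend contour (the zero locus of a
#' deviation field s_g set by the bend radius and |g|) crosses the field;
#' on the far side of the dislocation line the contour is displaced along
#' the line by f(phi_g) = A arctan(B cos^2(phi_g - C)), and for
#' reflections within 20 degrees of the line direction an additional
#' planted twist encodes the screw handedness. Disc intensity follows a
#' Gaussian rocking profile exp(-s_g^2 / 2 sigma_s^2); the direct beam
#' carries the residual intensity; counts are Poisson-drawn so the
#' expected per-pattern total equals the dose.
#'
#' @param spec a [SimulationSpec-class].
#' @return list with `dataset` (a [Dataset4D-class]) and `truth`
#'   (a [GroundTruth-class]).
#' @export
simulateDataset <- function(spec) {
  stopifnot(is(spec, "SimulationSpec"))
  methods::validObject(spec)
  hadSeed <- exists(".Random.seed", envir = globalenv())
  if (hadSeed) oldSeed <- get(".Random.seed", envir = globalenv())
  set.seed(spec@seed)
  on.exit(if (hadSeed) assign(".Random.seed", oldSeed, envir = globalenv()))

  ny <- spec@scanShape[1]; nx <- spec@scanShape[2]
  st <- spec@scanStep
  npos <- ny * nx
  gx <- rep((seq_len(nx) - 1) * st, each = ny)    # x per position
  gy <- rep((seq_len(ny) - 1) * st, times = nx)   # y per position
  pts <- cbind(gx, gy)
  poly <- spec@line@polyline
  frame <- .polylineFrame(poly, pts)
  farSide <- frame$offset > 0
  uDir <- .polylinePoint(poly, .polylineLength(poly) / 2)$dir
  uAz <- lineAzimuth(spec@line)
  Rnm <- spec@curvatureRadius * 1e3
  nHat <- .dirVec(spec@bendAzimuth)

  refl <- spec@reflections
  nref <- nrow(refl)
  mags <- sqrt(refl$kx^2 + refl$ky^2)
  phis <- .wrap360(.rad2deg(atan2(refl$ky, refl$kx)) + spec@rotationOffset)
  fPlant <- modelF(phis, spec@ampA, spec@shapeB, spec@phaseC)
  twisted <- spec@handedness != 0 & .acuteAngle(phis, uAz) <= 20
  Ltot <- .polylineLength(poly)
  anchorS <- Ltot * (0.30 + 0.40 * (seq_len(nref) - 0.5) / nref)

  # detector templates: unit-sum Gaussian discs
  nky <- spec@detShape[1]; nkx <- spec@detShape[2]
  bc <- c((nky + 1) / 2, (nkx + 1) / 2)
  sigPx <- (0.25 * discDiameterReciprocal(spec@geometry)) / spec@detectorCal
  discAt <- function(rowc, colc) {
    d2 <- outer((seq_len(nky) - rowc)^2, (seq_len(nkx) - colc)^2, "+")
    tmp <- exp(-d2 / (2 * sigPx^2))
    as.numeric(tmp / sum(tmp))
  }
  artShift <- if (!is.na(spec@artifactRow)) {
    (gy >= (spec@artifactRow - 1) * st) * spec@artifactJumpPx * st
  } else 0

  Ifrac <- matrix(0, npos, nref)
  for (j in seq_len(nref)) {
    p0 <- .polylinePoint(poly, anchorS[j])$p
    anchorFar <- p0 + fPlant[j] * uDir
    nj <- if (twisted[j])
      .dirVec(spec@bendAzimuth + spec@twistDeg * spec@handedness) else nHat
    dNear <- (pts[, 1] - p0[1]) * nHat[1] + (pts[, 2] - p0[2]) * nHat[2]
    dFar <- (pts[, 1] - anchorFar[1]) * nj[1] +
            (pts[, 2] - anchorFar[2]) * nj[2]
    dperp <- ifelse(farSide, dFar, dNear) + artShift
    sg <- mags[j] * dperp / Rnm                       # deviation, 1/Angstrom
    Ifrac[, j] <- spec@diffractedFraction *
      exp(-sg^2 / (2 * spec@rockingSigma^2))
  }
  directFrac <- pmax(1 - rowSums(Ifrac), 0)

  E <- outer(directFrac, discAt(bc[1], bc[2]))
  for (j in seq_len(nref)) {
    rc <- c(bc[1] - refl$ky[j] / spec@detectorCal,
            bc[2] + refl$kx[j] / spec@detectorCal)
    E <- E + outer(Ifrac[, j], discAt(rc[1], rc[2]))
  }
  E <- E * spec@dose
  cnt <- stats::rpois(length(E), E)
  dim(cnt) <- c(ny, nx, nky, nkx)

  ds <- dataset4D(cnt, scanStep = st, detectorCal = spec@detectorCal,
                  rotationOffset = spec@rotationOffset,
                  geometry = spec@geometry)
  truth <- methods::new("GroundTruth",
    table = data.frame(kx = refl$kx, ky = refl$ky, magnitude = mags,
                       phi = phis, displacement = fPlant,
                       twisted = twisted, anchorS = anchorS),
    bAzimuth = if (spec@ampA > 0) .wrap180(spec@phaseC) else NA_real_,
    handedness = if (spec@handedness > 0) "right"
                 else if (spec@handedness < 0) "left" else "none",
    artifactRows = if (is.na(spec@artifactRow)) integer()
                   else as.integer(spec@artifactRow),
    seed = spec@seed, spec = spec)
  list(dataset = ds, truth = truth)
}

# JSON-serializable view of a GroundTruth
.truthAsList <- function(truth) {
  list(b_azimuth_deg = truth@bAzimuth, handedness = truth@handedness,
       artifact_rows = truth@artifactRows, seed = truth@seed,
       amp_A_nm = truth@spec@ampA, shape_B = truth@spec@shapeB,
       phase_C_deg = truth@spec@phaseC,
       line_polyline_nm = unname(truth@spec@line@polyline),
       reflections = truth@table)
}

#' Write the documented fixture gallery
#'
#' Generates the standard validation scenes (null, edge B perpendicular
#' to u, screw B parallel to u, mixed 45 degrees, uniform-shift artifact,
#' and a low-dose case at ~5 electrons per square Angstrom fluence
#' equivalent), each with a ground-truth JSON sidecar. Deterministic for
#' fixed seeds: re-running produces byte-identical sidecars.
#'
#' @param outDir output directory.
#' @param seed base seed; fixture i uses `seed + i - 1`.
#' @param scanShape scan shape passed to every fixture.
#' @param writeDatasets also write the 4D containers (large); sidecars are
#'   always written.
#' @return data.frame manifest (fixture, seed, planted azimuth,
#'   handedness, paths), invisibly carrying the specs as attribute
#'   `specs`.
#' @export
makeFixtureSuite <- function(outDir, seed = 1L, scanShape = c(64L, 64L),
                             writeDatasets = FALSE) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  uAz <- 30  # default line azimuth
  lowDose <- 6241.5 * 5 / 8.8
  mk <- function(i, ...) simulationSpec(scanShape = scanShape,
                                        seed = seed + i - 1L, ...)
  specs <- list(
    null = mk(1, ampA = 0),
    edge = mk(2, phaseC = .wrap180(uAz + 90)),
    screw = mk(3, phaseC = uAz, handedness = 1),
    mixed = mk(4, phaseC = .wrap180(uAz + 45), handedness = -1),
    artifact = mk(5, phaseC = .wrap180(uAz + 45),
                  artifactRow = round(scanShape[1] * 0.78)),
    lowdose = mk(6, phaseC = uAz, handedness = 1, dose = lowDose))
  rows <- lapply(names(specs), function(nm) {
    sim <- simulateDataset(specs[[nm]])
    side <- file.path(outDir, paste0(nm, "_truth.json"))
    jsonlite::write_json(.truthAsList(sim$truth), side, auto_unbox = TRUE,
                         digits = 10, pretty = TRUE)
    dsPath <- NA_character_
    if (writeDatasets) {
      dsPath <- file.path(outDir, paste0(nm, "_data"))
      saveDataset4D(sim$dataset, dsPath)
    }
    data.frame(fixture = nm, seed = specs[[nm]]@seed,
               bAzimuth = sim$truth@bAzimuth,
               handedness = sim$truth@handedness,
               truthPath = side, dataPath = dsPath)
  })
  out <- do.call(rbind, rows)
  attr(out, "specs") <- specs
  invisible(out)
}
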