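# S4 class definitions for the SED dislocation-analysis pipeline.
#
# Coordinate conventions (used everywhere):
#  * Arrays are stored [scan_row, scan_col, det_row, det_col]; row indices
#    increase downward in storage order.
#  * All azimuths are reported in a mathematical y-up frame:
#    azimuth(v) = atan2(-d_row, d_col), degrees.
#  * GVector azimuths are rotation-corrected (scan-to-detector rotation
#    offset applied), so detector and scan azimuths are commensurable.

#' Acquisition geometry of a scanning electron diffraction experiment
#'
#' Holds the probe-forming parameters needed for dose and resolution
#' arithmetic: accelerating voltage, convergence semiangle, probe current
#' and dwell time.
#'
#' @slot kV accelerating voltage in kilovolts.
#' @slot alpha convergence semiangle in milliradians.
#' @slot current probe current in picoamperes.
#' @slot dwell dwell time per probe position in milliseconds.
#'
#' @seealso [probeDiameter()], [fluencePerScan()], [discDiameterReciprocal()]
#' @export
setClass("AcquisitionGeometry",
  representation(kV = "numeric", alpha = "numeric",
                 current = "numeric", dwell = "numeric"),
  prototype(kV = 300, alpha = 0.8, current = 1, dwell = 1))

setValidity("AcquisitionGeometry", function(object) {
  msg <- character()
  for (s in c("kV", "alpha", "current", "dwell")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be a single positive number", s))
  }
  if (length(msg)) msg else TRUE
})

#' Per-pattern centering and distortion calibration
#'
#' Records the sub-pixel shifts applied to move the direct beam to the
#' detector centre, the affine matrix used to correct residual elliptical
#' distortion, and the scan-to-detector rotation offset.
#'
#' @slot centerShiftMap numeric array (scan_y, scan_x, 2) of applied
#'   (row, col) shifts in pixels.
#' @slot affine invertible 2x2 matrix with positive determinant.
#' @slot rotationOffset scan-to-detector rotation offset in degrees.
#' @export
setClass("Calibration",
  representation(centerShiftMap = "array", affine = "matrix",
                 rotationOffset = "numeric"),
  prototype(affine = diag(2), rotationOffset = 0))

setValidity("Calibration", function(object) {
  a <- object@affine
  if (!identical(dim(a), c(2L, 2L))) return("'affine' must be 2x2")
  if (!all(is.finite(a)) || det(a) <= 0)
    return("'affine' must be finite with det > 0")
  TRUE
})

#' Calibrated four-dimensional SED dataset
#'
#' A 4D-STEM / SED acquisition: a 2D raster of probe positions, each
#' holding a full 2D electron diffraction pattern, together with the
#' axis calibrations and acquisition metadata required for quantitative
#' analysis.
#'
#' @slot counts non-negative 4D array (scan_y, scan_x, k_y, k_x) of
#'   electron counts.
#' @slot scanStep scan sampling in nm per pixel.
#' @slot detectorCal detector sampling in reciprocal Angstrom per pixel.
#' @slot rotationOffset scan-to-detector azimuth rotation in degrees.
#' @slot beamCenter detector (row, col) of the direct beam, sub-pixel.
#' @slot geometry an [AcquisitionGeometry-class] object.
#' @slot calibrated logical flag; `FALSE` when calibrations were filled
#'   with documented defaults on load.
#' @export
setClass("Dataset4D",
  representation(counts = "array", scanStep = "numeric",
                 detectorCal = "numeric", rotationOffset = "numeric",
                 beamCenter = "numeric", geometry = "AcquisitionGeometry",
                 calibrated = "logical"),
  prototype(scanStep = 1, detectorCal = 1, rotationOffset = 0,
            calibrated = TRUE))

setValidity("Dataset4D", function(object) {
  d <- dim(object@counts)
  if (length(d) != 4L) return("'counts' must be a 4D array")
  if (any(d < 8L)) return("scan and detector dimensions must be >= 8")
  if (anyNA(object@counts) || any(!is.finite(object@counts)))
    return("'counts' must be finite")
  if (min(object@counts) < 0) return("'counts' must be non-negative")
  if (length(object@detectorCal) != 1L || object@detectorCal <= 0)
    return("'detectorCal' must be a single positive number")
  if (length(object@scanStep) != 1L || object@scanStep <= 0)
    return("'scanStep' must be a single positive number")
  bc <- object@beamCenter
  if (length(bc) != 2L || any(bc < 1) || bc[1] > d[3] || bc[2] > d[4])
    return("'beamCenter' must lie inside the detector bounds")
  TRUE
})

#' A consolidated diffraction vector
#'
#' One Bragg reflection observed across the scan: its reciprocal-space
#' coordinate in the corrected detector frame, magnitude, rotation-corrected
#' azimuth and (optionally) Miller indices.
#'
#' @slot k length-2 numeric, (k_x, k_y) in inverse Angstrom, y-up frame.
#' @slot magnitude |k| in inverse Angstrom.
#' @slot phi azimuth in degrees, `[0, 360)`, rotation-corrected.
#' @slot hkl integer triple or empty when unindexed.
#' @slot usable logical; whether the reflection qualifies for metrology.
#' @export
setClass("GVector",
  representation(k = "numeric", magnitude = "numeric", phi = "numeric",
                 hkl = "integer", usable = "logical"),
  prototype(hkl = integer(), usable = TRUE))

setValidity("GVector", function(object) {
  if (length(object@k) != 2L) return("'k' must be length 2")
  if (abs(object@magnitude - sqrt(sum(object@k^2))) > 1e-9)
    return("'magnitude' must equal |k| to 1e-9")
  if (object@phi < 0 || object@phi >= 360)
    return("'phi' must lie in [0, 360)")
  if (length(object@hkl) %in% c(0L, 3L)) TRUE else "'hkl' must be length 0 or 3"
})

#' Virtual dark-field image for one diffraction vector
#'
#' Real-space image formed by integrating, at every probe position, the
#' counts inside a small circular aperture centred on one Bragg disc.
#'
#' @slot image non-negative 2D matrix over scan coordinates.
#' @slot g the [GVector-class] the aperture was centred on.
#' @slot apertureRadius aperture radius in inverse Angstrom.
#' @slot scanStep scan sampling in nm per pixel (copied from the dataset).
#' @export
setClass("VDFImage",
  representation(image = "matrix", g = "GVector",
                 apertureRadius = "numeric", scanStep = "numeric"),
  prototype(scanStep = 1))

setValidity("VDFImage", function(object) {
  if (min(object@image) < 0) return("'image' must be non-negative")
  if (object@apertureRadius <= 0) return("'apertureRadius' must be > 0")
  TRUE
})

#' A dislocation line traced in the scan frame
#'
#' An ordered polyline (in nm) marking the dislocation core, with the
#' point order defining the positive sense used for signed displacements.
#'
#' @slot polyline n x 2 matrix of (x, y) scan-frame points in nm; y
#'   increases downward in storage, azimuths are reported y-up.
#' @slot positiveSense +1 to follow point order, -1 to reverse it.
#' @export
setClass("DislocationLine",
  representation(polyline = "matrix", positiveSense = "numeric"),
  prototype(positiveSense = 1))

setValidity("DislocationLine", function(object) {
  p <- object@polyline
  if (ncol(p) != 2L || nrow(p) < 2L)
    return("'polyline' must be an n x 2 matrix with n >= 2")
  seg <- diff(p)
  if (any(rowSums(seg^2) == 0)) return("consecutive points must be distinct")
  if (!object@positiveSense %in% c(-1, 1))
    return("'positiveSense' must be +1 or -1")
  TRUE
})

#' One bend-contour displacement measurement
#'
#' The signed displacement, along the dislocation line, between the
#' centerlines of the two bend-contour segments on either side of the
#' line, for one diffraction vector.
#'
#' @slot g the [GVector-class] measured.
#' @slot displacement signed displacement along the line's positive sense, nm.
#' @slot uncertainty standard error of the displacement, nm.
#' @slot usable logical; `FALSE` crossings are kept but excluded from fits.
#' @slot contourWidth median contour full width at half maximum, nm.
#' @slot note reason string when unusable.
#' @export
setClass("ContourCrossing",
  representation(g = "GVector", displacement = "numeric",
                 uncertainty = "numeric", usable = "logical",
                 contourWidth = "numeric", note = "character"),
  prototype(usable = TRUE, contourWidth = NA_real_, note = ""))

setValidity("ContourCrossing", function(object) {
  if (isTRUE(object@usable) &&
      (!is.finite(object@uncertainty) || object@uncertainty <= 0))
    return("usable crossings must carry a positive uncertainty")
  TRUE
})

#' Azimuthal displacement profile of one dislocation
#'
#' The collection of per-g bend-contour displacement measurements that is
#' fitted against the azimuthal displacement model.
#'
#' @slot crossings list of [ContourCrossing-class] objects, one per GVector.
#' @slot phiConvention free-text note on the azimuth convention.
#' @export
setClass("DisplacementProfile",
  representation(crossings = "list", phiConvention = "character"),
  prototype(phiConvention = "detector frame, rotation-corrected, y-up"))

setValidity("DisplacementProfile", function(object) {
  if (!all(vapply(object@crossings, is, TRUE, "ContourCrossing")))
    return("'crossings' must contain ContourCrossing objects")
  if (!any(vapply(object@crossings, slot, TRUE, "usable")))
    return("profile must contain at least one usable crossing")
  ph <- vapply(object@crossings, function(cr) cr@g@phi, 0)
  if (anyDuplicated(round(ph, 6)))
    return("at most one crossing per GVector azimuth")
  TRUE
})

#' Fitted azimuthal displacement model
#'
#' Result of the weighted nonlinear least-squares fit of
#' f(phi) = A * arctan(B * cos^2(phi - C)) to a displacement profile.
#' A carries the effective-curvature scaling (nm), B is a dimensionless
#' shape factor and C is the azimuth of maximum displacement, i.e. the
#' projected Burgers vector azimuth up to the intrinsic 180-degree
#' ambiguity.
#'
#' @slot ampA amplitude A in nm (>= 0).
#' @slot shapeB dimensionless shape factor B (>= 0).
#' @slot phaseC phase C in degrees, reported in `[0, 180)`; `NA` when the
#'   profile shows no resolvable distortion.
#' @slot ci 3 x 2 matrix of 95 percent confidence bounds (rows A, B, C).
#' @slot ciMethod how the intervals were obtained.
#' @slot residuals per-point weighted residuals.
#' @slot rms root-mean-square residual in nm.
#' @slot converged logical.
#' @slot noDistortion logical; `TRUE` for the degenerate all-zero profile.
#' @export
setClass("BurgersFit",
  representation(ampA = "numeric", shapeB = "numeric", phaseC = "numeric",
                 ci = "matrix", ciMethod = "character",
                 residuals = "numeric", rms = "numeric",
                 converged = "logical", noDistortion = "logical"),
  prototype(ciMethod = "seeded residual bootstrap", converged = TRUE,
            noDistortion = FALSE))

setValidity("BurgersFit", function(object) {
  if (object@noDistortion) return(TRUE)
  if (object@ampA < 0 || object@shapeB < 0)
    return("'ampA' and 'shapeB' must be non-negative")
  if (!is.na(object@phaseC) && (object@phaseC < 0 || object@phaseC >= 180))
    return("'phaseC' must be reported in [0, 180)")
  TRUE
})

#' Dislocation character call
#'
#' The geometric relation between the Burgers vector azimuth and the
#' local line direction: screw (B parallel to u), edge (B perpendicular
#' to u) or mixed, plus the handedness of any screw component.
#'
#' @slot angleBu acute angle between B and u in degrees, `[0, 90]`.
#' @slot label one of "edge", "screw", "mixed", "undetermined".
#' @slot handedness one of "left", "right", "undetermined".
#' @slot edgeComponentAzimuth azimuth of the edge component in degrees,
#'   or `NA` when absent.
#' @export
setClass("CharacterCall",
  representation(angleBu = "numeric", label = "character",
                 handedness = "character",
                 edgeComponentAzimuth = "numeric"),
  prototype(handedness = "undetermined", edgeComponentAzimuth = NA_real_))

setValidity("CharacterCall", function(object) {
  if (!object@label %in% c("edge", "screw", "mixed", "undetermined"))
    return("invalid character label")
  if (!object@handedness %in% c("left", "right", "undetermined"))
    return("invalid handedness")
  TRUE
})

#' Crystallographic unit cell
#'
#' Cell constants only; symmetry and atomic contents are outside the scope
#' of the geometric analysis performed here.
#'
#' @slot a,b,c cell lengths in Angstrom.
#' @slot alpha,beta,gamma cell angles in degrees.
#' @slot label free-text provenance label.
#' @export
setClass("UnitCell",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 alpha = "numeric", beta = "numeric", gamma = "numeric",
                 label = "character"),
  prototype(alpha = 90, beta = 90, gamma = 90, label = ""))

setValidity("UnitCell", function(object) {
  if (any(c(object@a, object@b, object@c) <= 0))
    return("cell lengths must be positive")
  ang <- c(object@alpha, object@beta, object@gamma)
  if (any(ang <= 0 | ang >= 180)) return("cell angles must lie in (0, 180)")
  if (!is.finite(cellVolume(object)) || cellVolume(object) <= 0)
    return("cell volume must be real and positive")
  TRUE
})

#' Synthetic scene specification
#'
#' Parameters of the ground-truthed generator: a thin, cylindrically bent
#' crystal (one straight bend contour per reflection, all sharing the bend
#' gradient direction) crossed by a straight in-plane dislocation that
#' displaces each contour along the line by the azimuthal displacement
#' model, imaged at a stated electron dose with Poisson counting noise.
#'
#' @slot scanShape integer (rows, cols) of the probe raster.
#' @slot scanStep scan sampling, nm per pixel.
#' @slot detShape integer (rows, cols) of the detector.
#' @slot detectorCal detector sampling, inverse Angstrom per pixel.
#' @slot geometry an [AcquisitionGeometry-class].
#' @slot reflections data.frame with columns kx, ky (inverse Angstrom,
#'   y-up) and optional h, k, l.
#' @slot curvatureRadius effective bending radius, micrometres.
#' @slot rockingSigma rocking-curve width sigma_s, inverse Angstrom.
#' @slot diffractedFraction peak diffracted intensity fraction per disc.
#' @slot line a [DislocationLine-class] (scan frame, nm).
#' @slot ampA,shapeB,phaseC planted displacement-model parameters
#'   (nm, dimensionless, degrees; phaseC in the scan frame).
#' @slot handedness +1 (right), -1 (left) or 0 (no screw twist planted).
#' @slot twistDeg contour twist applied to reflections near the line
#'   direction when a handedness is planted, degrees.
#' @slot bendAzimuth azimuth of the bend gradient (contour normal), degrees.
#' @slot artifactRow scan row at which a uniform mid-scan contour jump is
#'   inserted, or `NA` for none.
#' @slot artifactJumpPx size of that jump along the bend normal, scan px.
#' @slot dose expected electrons per pattern.
#' @slot rotationOffset scan-to-detector rotation offset written into the
#'   generated dataset, degrees.
#' @slot seed integer seed recorded in the output metadata.
#' @export
setClass("SimulationSpec",
  representation(scanShape = "integer", scanStep = "numeric",
                 detShape = "integer", detectorCal = "numeric",
                 geometry = "AcquisitionGeometry", reflections = "data.frame",
                 curvatureRadius = "numeric", rockingSigma = "numeric",
                 diffractedFraction = "numeric", line = "DislocationLine",
                 ampA = "numeric", shapeB = "numeric", phaseC = "numeric",
                 handedness = "numeric", twistDeg = "numeric",
                 bendAzimuth = "numeric", artifactRow = "numeric",
                 artifactJumpPx = "numeric", dose = "numeric",
                 rotationOffset = "numeric", seed = "integer"))

setValidity("SimulationSpec", function(object) {
  if (any(object@scanShape < 8L) || any(object@detShape < 8L))
    return("scan and detector shapes must be >= 8")
  if (object@ampA < 0) return("'ampA' must be >= 0")
  if (object@dose <= 0) return("'dose' must be positive")
  if (!object@handedness %in% c(-1, 0, 1))
    return("'handedness' must be -1, 0 or +1")
  r <- object@reflections
  if (!all(c("kx", "ky") %in% names(r)))
    return("'reflections' needs kx, ky columns")
  half <- pmin(object@detShape[1], object@detShape[2]) / 2 * object@detectorCal
  if (any(sqrt(r$kx^2 + r$ky^2) >= half))
    return("reflections must lie within the detector")
  TRUE
})

#' Ground truth of a synthetic scene
#'
#' Everything the generator planted, for closed-loop validation: the
#' per-reflection contour loci and displacements, the Burgers azimuth,
#' handedness, artifact rows and the seed.
#'
#' @slot table data.frame with one row per reflection: kx, ky, phi,
#'   planted displacement (nm), twist flag.
#' @slot bAzimuth planted Burgers-vector azimuth, degrees in `[0, 180)`.
#' @slot handedness "left", "right" or "none".
#' @slot artifactRows integer rows carrying the planted uniform jump onset.
#' @slot seed integer seed used.
#' @slot spec the originating [SimulationSpec-class].
#' @export
setClass("GroundTruth",
  representation(table = "data.frame", bAzimuth = "numeric",
                 handedness = "character", artifactRows = "integer",
                 seed = "integer", spec = "SimulationSpec"))
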