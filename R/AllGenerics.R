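# Generics and accessors. Slots are never accessed directly by user code.

#' @rdname Dataset4D-class
#' @param object,x a package object.
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))

#' @rdname Dataset4D-class
#' @export
setGeneric("scanStep", function(object) standardGeneric("scanStep"))

#' @rdname Dataset4D-class
#' @export
setGeneric("detectorCal", function(object) standardGeneric("detectorCal"))

#' @rdname Dataset4D-class
#' @export
setGeneric("rotationOffset", function(object) standardGeneric("rotationOffset"))

#' @rdname Dataset4D-class
#' @export
setGeneric("beamCenter", function(object) standardGeneric("beamCenter"))

#' @rdname Dataset4D-class
#' @export
setGeneric("acquisition", function(object) standardGeneric("acquisition"))

#' @rdname DisplacementProfile-class
#' @export
setGeneric("crossingTable", function(object) standardGeneric("crossingTable"))

#' @rdname BurgersFit-class
#' @export
setGeneric("fitCoefficients", function(object) standardGeneric("fitCoefficients"))

#' @rdname BurgersFit-class
#' @export
setGeneric("confint95", function(object) standardGeneric("confint95"))

#' @describeIn Dataset4D-class counts accessor.
setMethod("counts", "Dataset4D", function(object) object@counts)

#' @describeIn Dataset4D-class scan step (nm/px).
setMethod("scanStep", "Dataset4D", function(object) object@scanStep)

#' @describeIn Dataset4D-class detector calibration (inverse Angstrom/px).
setMethod("detectorCal", "Dataset4D", function(object) object@detectorCal)

#' @describeIn Dataset4D-class scan-to-detector rotation offset (deg).
setMethod("rotationOffset", "Dataset4D", function(object) object@rotationOffset)

#' @describeIn Dataset4D-class direct-beam detector coordinate (row, col).
setMethod("beamCenter", "Dataset4D", function(object) object@beamCenter)

#' @describeIn Dataset4D-class acquisition geometry.
setMethod("acquisition", "Dataset4D", function(object) object@geometry)

setMethod("show", "Dataset4D", function(object) {
  d <- dim(object@counts)
  cat(sprintf("Dataset4D: %d x %d scan, %d x %d detector\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  scan step %.3g nm/px, detector %.4g 1/Angstrom/px, rotation %.4g deg\n",
              object@scanStep, object@detectorCal, object@rotationOffset))
  g <- object@geometry
  cat(sprintf("  %g kV, alpha %g mrad, %g pA, %g ms%s\n", g@kV, g@alpha,
              g@current, g@dwell,
              if (object@calibrated) "" else "  [uncalibrated defaults]"))
})

setMethod("show", "GVector", function(object) {
  hk <- if (length(object@hkl)) paste0(" hkl=(",
          paste(object@hkl, collapse = " "), ")") else ""
  cat(sprintf("GVector |g|=%.4g 1/Angstrom, phi=%.2f deg%s%s\n",
              object@magnitude, object@phi, hk,
              if (object@usable) "" else " [unusable]"))
})

setMethod("show", "VDFImage", function(object) {
  cat(sprintf("VDFImage %d x %d, aperture %.3g 1/Angstrom, ",
              nrow(object@image), ncol(object@image), object@apertureRadius))
  show(object@g)
})

#' @describeIn DisplacementProfile-class one row per crossing: azimuth,
#'   displacement (nm), uncertainty (nm), usability and contour width.
setMethod("crossingTable", "DisplacementProfile", function(object) {
  do.call(rbind, lapply(object@crossings, function(cr) {
    data.frame(kx = cr@g@k[1], ky = cr@g@k[2], magnitude = cr@g@magnitude,
               phi = cr@g@phi, displacement = cr@displacement,
               uncertainty = cr@uncertainty, usable = cr@usable,
               contourWidth = cr@contourWidth, note = cr@note)
  }))
})

setMethod("show", "DisplacementProfile", function(object) {
  tab <- crossingTable(object)
  cat(sprintf("DisplacementProfile: %d crossings (%d usable)\n",
              nrow(tab), sum(tab$usable)))
})

#' @describeIn BurgersFit-class named coefficient vector (A, B, C).
setMethod("fitCoefficients", "BurgersFit", function(object)
  c(A = object@ampA, B = object@shapeB, C = object@phaseC))

#' @describeIn BurgersFit-class 95 percent confidence bounds.
setMethod("confint95", "BurgersFit", function(object) object@ci)

setMethod("show", "BurgersFit", function(object) {
  if (object@noDistortion) {
    cat("BurgersFit: no resolvable distortion (A pinned to 0)\n")
  } else {
    cat(sprintf(
      "BurgersFit: A=%.3g nm, B=%.3g, C=%.2f deg (rms %.3g nm, CI: %s)\n",
      object@ampA, object@shapeB, object@phaseC, object@rms, object@ciMethod))
  }
})

setMethod("show", "CharacterCall", function(object) {
  cat(sprintf("CharacterCall: %s (angle(B,u)=%.1f deg), handedness %s\n",
              object@label, object@angleBu, object@handedness))
})

setMethod("show", "UnitCell", function(object) {
  cat(sprintf("UnitCell %s: a=%.4g b=%.4g c=%.4g  alpha=%.4g beta=%.4g gamma=%.4g\n",
              object@label, object@a, object@b, object@c,
              object@alpha, object@beta, object@gamma))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %d reflections, B azimuth %.2f deg, handedness %s, seed %d\n",
    nrow(object@table), object@bAzimuth, object@handedness, object@seed))
})
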