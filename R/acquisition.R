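# Acquisition-geometry arithmetic: relativistic electron wavelength,
# diffraction-limited probe size, per-scan fluence and disc diameter.

# CODATA 2018 constants (SI)
.planck <- 6.62607015e-34
.emass <- 9.1093837015e-31
.echarge <- 1.602176634e-19
.clight <- 2.99792458e8

#' Construct an acquisition geometry
#'
#' @param kV accelerating voltage in kilovolts.
#' @param alpha convergence semiangle in milliradians.
#' @param current probe current in picoamperes.
#' @param dwell dwell time in milliseconds.
#' @return an [AcquisitionGeometry-class] object.
#' @examples
#' geom <- acquisitionGeometry(300, 0.8)
#' probeDiameter(geom)
#' @export
acquisitionGeometry <- function(kV = 300, alpha = 0.8, current = 1, dwell = 1) {
  methods::new("AcquisitionGeometry", kV = kV, alpha = alpha,
               current = current, dwell = dwell)
}

#' Relativistic electron wavelength
#'
#' lambda = h / sqrt(2 m0 e V (1 + e V / (2 m0 c^2))), CODATA constants.
#'
#' @param kV accelerating voltage in kilovolts, in (10, 1000).
#' @return wavelength in Angstrom.
#' @examples
#' electronWavelength(300)  # ~0.0197 Angstrom
#' @export
electronWavelength <- function(kV) {
  stopifnot(is.numeric(kV), kV > 10, kV < 1000)
  V <- kV * 1e3
  lam <- .planck / sqrt(2 * .emass * .echarge * V *
                          (1 + .echarge * V / (2 * .emass * .clight^2)))
  lam * 1e10
}

#' Diffraction-limited probe diameter
#'
#' d_diff = 1.22 lambda / alpha for a nearly parallel probe formed with
#' convergence semiangle alpha. At 300 kV and 0.8 mrad this is ~3 nm.
#'
#' @param geom an [AcquisitionGeometry-class].
#' @return probe diameter in nm.
#' @export
probeDiameter <- function(geom) {
  stopifnot(is(geom, "AcquisitionGeometry"))
  if (geom@alpha <= 0) stop("convergence semiangle must be positive")
  lamA <- electronWavelength(geom@kV)
  1.22 * (lamA * 0.1) / (geom@alpha * 1e-3)   # Angstrom -> nm
}

#' Electron fluence delivered in a single scan
#'
#' Electrons per probe position (current x dwell / e) divided by the
#' disc-like probe area pi d_diff^2 / 4. Approximately 8.8 e-/A^2 at
#' 300 kV and 5.4 e-/A^2 at 200 kV for 1 pA x 1 ms at 0.8 mrad.
#'
#' @param geom an [AcquisitionGeometry-class].
#' @return fluence in electrons per square Angstrom.
#' @export
fluencePerScan <- function(geom) {
  stopifnot(is(geom, "AcquisitionGeometry"))
  ne <- geom@current * 1e-12 * geom@dwell * 1e-3 / .echarge
  dA <- probeDiameter(geom) * 10            # nm -> Angstrom
  ne / (pi * dA^2 / 4)
}

#' Diffraction-disc diameter in reciprocal space
#'
#' 2 alpha / lambda: the diameter of each Bragg disc set by the probe
#' convergence semiangle (~0.08 1/Angstrom at 300 kV, 0.8 mrad).
#'
#' @param geom an [AcquisitionGeometry-class].
#' @return disc diameter in inverse Angstrom.
#' @export
discDiameterReciprocal <- function(geom) {
  stopifnot(is(geom, "AcquisitionGeometry"))
  if (geom@alpha <= 0) stop("convergence semiangle must be positive")
  2 * geom@alpha * 1e-3 / electronWavelength(geom@kV)
}

#' Expected electrons per diffraction pattern
#'
#' current x dwell / elementary charge; ~6.24e3 electrons for 1 pA, 1 ms.
#'
#' @param geom an [AcquisitionGeometry-class].
#' @return expected electron count per pattern.
#' @export
electronsPerPattern <- function(geom) {
  stopifnot(is(geom, "AcquisitionGeometry"))
  geom@current * 1e-12 * geom@dwell * 1e-3 / .echarge
}
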