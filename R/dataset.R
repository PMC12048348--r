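# Dataset4D construction, container I/O, centering/distortion correction,
# binning, and whole-pattern images (ADF, mean pattern).

#' Construct a calibrated 4D dataset
#'
#' @param counts 4D non-negative array (scan_y, scan_x, k_y, k_x).
#' @param scanStep scan sampling, nm per pixel.
#' @param detectorCal detector sampling, inverse Angstrom per pixel.
#' @param rotationOffset scan-to-detector rotation offset, degrees.
#' @param beamCenter detector (row, col) of the direct beam; defaults to
#'   the geometric centre.
#' @param geometry an [AcquisitionGeometry-class].
#' @param calibrated logical flag, `FALSE` when calibrations are defaults.
#' @return a [Dataset4D-class] object.
#' @export
dataset4D <- function(counts, scanStep = 1, detectorCal = 1,
                      rotationOffset = 0, beamCenter = NULL,
                      geometry = acquisitionGeometry(), calibrated = TRUE) {
  d <- dim(counts)
  if (is.null(beamCenter)) beamCenter <- c((d[3] + 1) / 2, (d[4] + 1) / 2)
  methods::new("Dataset4D", counts = counts, scanStep = scanStep,
               detectorCal = detectorCal, rotationOffset = rotationOffset,
               beamCenter = beamCenter, geometry = geometry,
               calibrated = calibrated)
}

# counts as (n_scan_positions x n_detector_pixels) matrix, scan positions
# in column-major (row fastest) order, detector pixels likewise.
.asPatternMatrix <- function(ds) {
  d <- dim(ds@counts)
  m <- ds@counts
  dim(m) <- c(d[1] * d[2], d[3] * d[4])
  m
}

# detector |k| grid (inverse Angstrom) about the beam center
.kRadiusGrid <- function(ds) {
  d <- dim(ds@counts)
  rr <- (seq_len(d[3]) - ds@beamCenter[1]) * ds@detectorCal
  cc <- (seq_len(d[4]) - ds@beamCenter[2]) * ds@detectorCal
  sqrt(outer(rr^2, cc^2, "+"))
}

## ---------------------------------------------------------------- I/O ----

#' Save / load a 4D dataset container
#'
#' The container is a directory holding `meta.yaml` (axis calibrations,
#' acquisition metadata, array shape, storage type) and `counts.bin`
#' (the counts array, little-endian, column-major, int32 when all counts
#' are integral and within range, float64 otherwise). The round trip is
#' lossless. When calibrations are absent from the sidecar the dataset is
#' loaded with defaults of 1.0 and flagged uncalibrated.
#'
#' @param ds a [Dataset4D-class].
#' @param path container directory.
#' @return `saveDataset4D` returns `path` invisibly; `loadDataset4D`
#'   returns a [Dataset4D-class].
#' @export
saveDataset4D <- function(ds, path) {
  stopifnot(is(ds, "Dataset4D"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  cnt <- ds@counts
  asInt <- all(cnt == round(cnt)) && max(cnt) <= .Machine$integer.max
  meta <- list(
    format = "sedisloc-4d", version = 1L,
    shape = as.integer(dim(cnt)),
    dtype = if (asInt) "int32" else "float64",
    scan_step_nm = ds@scanStep,
    detector_cal_invA = ds@detectorCal,
    rotation_offset_deg = ds@rotationOffset,
    beam_center_px = as.numeric(ds@beamCenter),
    calibrated = ds@calibrated,
    kV = ds@geometry@kV, alpha_mrad = ds@geometry@alpha,
    current_pA = ds@geometry@current, dwell_ms = ds@geometry@dwell)
  yaml::write_yaml(meta, file.path(path, "meta.yaml"))
  con <- file(file.path(path, "counts.bin"), "wb")
  on.exit(close(con))
  if (asInt) writeBin(as.integer(cnt), con, size = 4L, endian = "little")
  else writeBin(as.numeric(cnt), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname saveDataset4D
#' @export
loadDataset4D <- function(path) {
  metaFile <- file.path(path, "meta.yaml")
  binFile <- file.path(path, "counts.bin")
  if (!file.exists(metaFile) || !file.exists(binFile))
    stop("not a 4D container: missing meta.yaml or counts.bin in ", path)
  meta <- yaml::read_yaml(metaFile)
  if (!identical(meta$format, "sedisloc-4d"))
    stop("format error: unrecognized container format")
  shape <- as.integer(unlist(meta$shape))
  if (length(shape) != 4L) stop("format error: container lacks a 4D signal")
  n <- prod(shape)
  con <- file(binFile, "rb")
  on.exit(close(con))
  cnt <- if (identical(meta$dtype, "int32")) {
    as.numeric(readBin(con, "integer", n = n, size = 4L, endian = "little"))
  } else readBin(con, "numeric", n = n, size = 8L, endian = "little")
  if (length(cnt) != n) stop("format error: truncated counts array")
  if (any(!is.finite(cnt))) stop("data error: non-finite counts")
  dim(cnt) <- shape
  calibrated <- !is.null(meta$detector_cal_invA) && !is.null(meta$scan_step_nm)
  if (!calibrated)
    warning("container lacks calibration; loaded with cal = 1.0 (uncalibrated)")
  geom <- acquisitionGeometry(
    kV = meta$kV %||% 300, alpha = meta$alpha_mrad %||% 0.8,
    current = meta$current_pA %||% 1, dwell = meta$dwell_ms %||% 1)
  dataset4D(cnt,
            scanStep = meta$scan_step_nm %||% 1,
            detectorCal = meta$detector_cal_invA %||% 1,
            rotationOffset = meta$rotation_offset_deg %||% 0,
            beamCenter = if (is.null(meta$beam_center_px)) NULL
                         else as.numeric(unlist(meta$beam_center_px)),
            geometry = geom,
            calibrated = isTRUE(meta$calibrated %||% calibrated) && calibrated)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ------------------------------------------- centering and correction ----

#' Center the direct beam and correct elliptical distortion
#'
#' Each diffraction pattern is cross-correlated against a disc template to
#' locate the direct beam, then shifted (sub-pixel, Fourier interpolation
#' with edge apodization in the correlation step) so the beam sits at the
#' geometric detector centre. The inverse of the supplied affine matrix is
#' then applied about the centre to undo residual elliptical distortion.
#'
#' @param ds a [Dataset4D-class] with the direct beam visible everywhere.
#' @param referenceDiscRadius radius of the disc template, detector px.
#' @param affine 2x2 distortion matrix to correct (identity = no-op).
#' @param significance minimum correlation-peak significance (peak / rms
#'   of the correlation surface); patterns below it abort centering.
#' @return list with elements `dataset` (centred [Dataset4D-class]) and
#'   `calibration` (a [Calibration-class] recording per-pattern shifts).
#' @export
centerAndCorrect <- function(ds, referenceDiscRadius = 3, affine = diag(2),
                             significance = 4) {
  stopifnot(is(ds, "Dataset4D"))
  d <- dim(ds@counts)
  ctr <- c((d[3] + 1) / 2, (d[4] + 1) / 2)
  rr <- outer((seq_len(d[3]) - ctr[1])^2, (seq_len(d[4]) - ctr[2])^2, "+")
  template <- exp(-rr / (2 * (referenceDiscRadius / 1.5)^2))
  shifts <- array(0, c(d[1], d[2], 2))
  out <- ds@counts
  identityAffine <- isTRUE(all.equal(affine, diag(2), tolerance = 1e-12))
  bad <- NULL
  comWin <- max(2, round(referenceDiscRadius))
  for (ix in seq_len(d[2])) for (iy in seq_len(d[1])) {
    pat <- ds@counts[iy, ix, , ]
    xc <- .xcorrShift(pat, template)
    if (xc$significance < significance) {
      bad <- rbind(bad, c(iy, ix)); next
    }
    sh <- xc$shift          # beam sits at ctr + sh; move it back by -sh
    # centre-of-mass refinement of the beam position around the
    # correlation estimate (the parabolic peak alone is good to ~0.2 px)
    com <- tryCatch(refineCOM(pat, ctr + sh, window = comWin),
                    error = function(e) NULL)
    if (!is.null(com) && sqrt(sum((com - ctr - sh)^2)) < 2) sh <- com - ctr
    shifts[iy, ix, ] <- sh
    pp <- if (max(abs(sh)) > 1e-3) .fourierShift(pat, -sh[1], -sh[2]) else pat
    if (!identityAffine) pp <- .affineResample(pp, affine, ctr)
    out[iy, ix, , ] <- pmax(pp, 0)
  }
  if (!is.null(bad))
    stop("centering failure: correlation peak below significance at scan ",
         "positions (row, col): ",
         paste(apply(bad, 1, paste, collapse = ","), collapse = "; "))
  cal <- methods::new("Calibration", centerShiftMap = shifts,
                      affine = affine, rotationOffset = ds@rotationOffset)
  dsOut <- ds
  dsOut@counts <- out
  dsOut@beamCenter <- ctr
  list(dataset = dsOut, calibration = cal)
}

## --------------------------------------------------------- reductions ----

#' Bin diffraction patterns
#'
#' Sums counts in `factor` x `factor` detector blocks (cropping trailing
#' rows/columns so the factor divides the detector dimensions) and scales
#' the detector calibration by `factor`. Total counts over the retained
#' region are conserved exactly for integer input.
#'
#' @param ds a [Dataset4D-class].
#' @param factor integer binning factor, >= 1.
#' @return a binned [Dataset4D-class].
#' @export
binPatterns <- function(ds, factor) {
  stopifnot(is(ds, "Dataset4D"))
  if (length(factor) != 1L || factor != round(factor) || factor <= 0)
    stop("'factor' must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(ds)
  d <- dim(ds@counts)
  nk <- (d[3] %/% factor) * factor
  nl <- (d[4] %/% factor) * factor
  cnt <- ds@counts[, , seq_len(nk), seq_len(nl), drop = FALSE]
  m <- cnt; dim(m) <- c(d[1] * d[2], nk * nl)
  # sparse aggregation matrix: detector pixel -> binned pixel
  pix <- expand.grid(r = seq_len(nk), c = seq_len(nl))
  grp <- (ceiling(pix$r / factor)) + (ceiling(pix$c / factor) - 1L) * (nk %/% factor)
  S <- Matrix::sparseMatrix(i = seq_len(nk * nl), j = grp, x = 1,
                            dims = c(nk * nl, (nk %/% factor) * (nl %/% factor)))
  mb <- as.matrix(m %*% S)
  dim(mb) <- c(d[1], d[2], nk %/% factor, nl %/% factor)
  dsOut <- ds
  dsOut@counts <- mb
  dsOut@detectorCal <- ds@detectorCal * factor
  dsOut@beamCenter <- (ds@beamCenter - 0.5) / factor + 0.5
  dsOut
}

#' Annular dark-field image
#'
#' Integrates each pattern over the annulus `rIn <= |k| <= rOut` about the
#' beam centre (membership by pixel-centre radius), producing a scan-shaped
#' image dominated by diffraction contrast.
#'
#' @param ds a centred [Dataset4D-class].
#' @param rIn,rOut annulus radii in inverse Angstrom (defaults 0.12 and 1).
#' @return a scan-shaped numeric matrix.
#' @export
adfImage <- function(ds, rIn = 0.12, rOut = 1.0) {
  stopifnot(is(ds, "Dataset4D"), rIn >= 0, rIn < rOut)
  kr <- .kRadiusGrid(ds)
  if (rOut > max(kr))
    warning("outer radius extends beyond the detector edge; annulus truncated")
  mask <- as.numeric(kr >= rIn & kr <= rOut)
  img <- .asPatternMatrix(ds) %*% mask
  matrix(img, dim(ds@counts)[1], dim(ds@counts)[2])
}

#' Mean diffraction pattern
#'
#' Arithmetic mean over all (or masked) scan positions.
#'
#' @param ds a [Dataset4D-class].
#' @param scanMask optional logical scan-shaped matrix selecting positions.
#' @return a detector-shaped numeric matrix.
#' @export
meanPattern <- function(ds, scanMask = NULL) {
  stopifnot(is(ds, "Dataset4D"))
  d <- dim(ds@counts)
  m <- .asPatternMatrix(ds)
  if (!is.null(scanMask)) {
    sel <- as.logical(scanMask)
    if (!any(sel)) stop("empty scan mask")
    m <- m[sel, , drop = FALSE]
  }
  matrix(colMeans(m), d[3], d[4])
}

#' Square-root display transform
#'
#' Returns sqrt(pmax(x, 0)), the display stretch conventionally applied to
#' diffraction patterns so low- and high-intensity features are visible
#' together. A display transform only; never applied before quantitative
#' steps.
#'
#' @param img numeric matrix.
#' @return transformed matrix.
#' @export
sqrtDisplay <- function(img) sqrt(pmax(img, 0))

#' Export an image as 8-bit PNG
#'
#' Linear (or square-root) stretch of a matrix to `[0, 1]`, written with
#' the png package.
#'
#' @param img numeric matrix.
#' @param path output file.
#' @param sqrtStretch apply [sqrtDisplay()] first.
#' @return `path`, invisibly.
#' @export
exportImagePNG <- function(img, path, sqrtStretch = FALSE) {
  if (sqrtStretch) img <- sqrtDisplay(img)
  rng <- range(img)
  z <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  png::writePNG(z, path)
  invisible(path)
}
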