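# End-to-end orchestration: centering -> g-vector consolidation -> VDF
# reconstruction -> artifact screening -> contour metrology -> model fit
# -> Burgers assignment, plus the polar-plot figure.

# Automatic near/far seed pair for a VDF: on each side of the line, the
# brightest (smoothed) pixel within a perpendicular-offset band and within
# the along-line extent of the polyline.
.autoSeedPair <- function(v, line, offsetRange = c(7, 26),
                          smoothing = 2 * v@scanStep) {
  st <- v@scanStep
  img <- .gaussBlur(v@image, smoothing / st)
  nr <- nrow(img); nc <- ncol(img)
  polyPx <- (line@polyline / st) + 1
  gr <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  fr <- .polylineFrame(polyPx, cbind(gr$col, gr$row))
  L <- .polylineLength(polyPx)
  inS <- fr$s >= -2 & fr$s <= L + 2
  val <- img[cbind(gr$row, gr$col)]
  pick <- function(sgn) {
    sel <- inS & (fr$offset * sgn) >= offsetRange[1] &
      (fr$offset * sgn) <= offsetRange[2]
    if (!any(sel)) stop("no candidate seed on one side of the line")
    i <- which(sel)[which.max(val[sel])]
    c((gr$col[i] - 1) * st, (gr$row[i] - 1) * st)
  }
  rbind(near = pick(-1), far = pick(+1))
}

# Mask scan rows outside the largest contiguous unflagged block containing
# the dislocation line's midpoint (used after a uniform-shift detection).
.maskFlaggedRows <- function(v, flaggedRows, line) {
  nr <- nrow(v@image)
  # rows from a flagged onset onward are coherently shifted relative to the
  # block before it; keep only the contiguous unflagged block holding the
  # dislocation line's midpoint
  ok <- !(seq_len(nr) %in% as.integer(flaggedRows))
  midRow <- round(mean(line@polyline[, 2]) / v@scanStep + 1)
  blocks <- rle(ok)
  ends <- cumsum(blocks$lengths)
  starts <- ends - blocks$lengths + 1
  keep <- rep(FALSE, nr)
  for (b in seq_along(blocks$values)) {
    if (blocks$values[b] && midRow >= starts[b] && midRow <= ends[b])
      keep[starts[b]:ends[b]] <- TRUE
  }
  if (!any(keep)) keep <- ok
  out <- v
  out@image[!keep, ] <- 0
  out
}

#' Analyze one dislocation in a 4D dataset
#'
#' Runs the full chain: pattern centering and distortion correction,
#' scan-wide g-vector consolidation, VDF reconstruction for every usable
#' reflection, uniform-shift artifact screening, bend-contour displacement
#' metrology at the dislocation line, weighted model fitting, and the
#' Burgers-vector, invisibility, character and handedness calls. When a
#' unit cell and zone axis are supplied the fitted azimuth is also matched
#' to candidate lattice directions and a slip system assigned.
#'
#' @param ds a [Dataset4D-class].
#' @param line a [DislocationLine-class] (scan frame, nm).
#' @param cell optional [UnitCell-class].
#' @param zone optional integer zone-axis triple (with `cell`).
#' @param apertureRadius VDF aperture radius, inverse Angstrom.
#' @param sampleFraction pattern subsample fraction for disc finding.
#' @param clusterTol g-vector clustering tolerance, inverse Angstrom.
#' @param seed seed for the subsample and bootstrap.
#' @param center run [centerAndCorrect()] first (disable when the input
#'   is already centred).
#' @param affine distortion matrix passed to [centerAndCorrect()].
#' @param nBoot bootstrap replicates for the fit confidence intervals.
#' @return a list report: `gvectors`, `vdfs`, `flaggedRows`, `profile`,
#'   `fit`, `bAzimuth`, `invisibility`, `character`, `handedness`,
#'   `match`, `slip`, `qc`.
#' @export
analyzeDislocation <- function(ds, line, cell = NULL, zone = NULL,
                               apertureRadius = 0.02, sampleFraction = 0.05,
                               clusterTol = 0.02, seed = 1L, center = TRUE,
                               affine = diag(2), nBoot = 200) {
  stopifnot(is(ds, "Dataset4D"), is(line, "DislocationLine"))
  qc <- character()
  if (center) {
    rpx <- 0.5 * discDiameterReciprocal(ds@geometry) / ds@detectorCal
    ds <- centerAndCorrect(ds, referenceDiscRadius = max(rpx, 2),
                           affine = affine)$dataset
  }
  gv <- consolidateGVectors(ds, sampleFraction = sampleFraction,
                            clusterTol = clusterTol, seed = seed)
  if (!length(gv)) stop("stage gvectors: no reflections found")
  vdfs <- lapply(gv, function(g) vdf(ds, g, apertureRadius))
  usable <- vapply(vdfs, vdfUsable, TRUE)
  if (!any(usable)) stop("stage vdf: no usable reflections")
  vdfs <- vdfs[usable]; gv <- gv[usable]
  flagged <- if (length(vdfs) >= 3) detectUniformShift(vdfs) else integer()
  if (length(flagged)) {
    qc <- c(qc, sprintf("uniform mid-scan shift flagged at rows %s; excluded",
                        paste(flagged, collapse = ",")))
    vdfs <- lapply(vdfs, .maskFlaggedRows, flaggedRows = flagged, line = line)
  }
  crossings <- lapply(vdfs, function(v) {
    sd <- tryCatch(.autoSeedPair(v, line), error = function(e) NULL)
    if (is.null(sd))
      return(methods::new("ContourCrossing", g = v@g,
                          displacement = NA_real_, uncertainty = NA_real_,
                          usable = FALSE, note = "no seed found"))
    measureDisplacement(v, line, sd)
  })
  profile <- buildProfile(crossings)
  nbad <- sum(!vapply(crossings, slot, TRUE, "usable"))
  if (nbad) qc <- c(qc, sprintf("%d unusable reflections excluded", nbad))
  fit <- fitDisplacementModel(profile, nBoot = nBoot, ciSeed = seed + 1000L)
  bAz <- burgersAzimuth(fit)
  inv <- if (!fit@noDistortion) invisibilitySet(profile, fit) else list()
  if (!is.null(attr(inv, "note"))) qc <- c(qc, attr(inv, "note"))
  chr <- classifyCharacter(bAz, line)
  hand <- "undetermined"
  uAz <- lineAzimuth(line)
  nearU <- which(vapply(gv, function(g) .acuteAngle(g@phi, uAz) <= 20, TRUE))
  if (length(nearU) >= 2 && !is.na(bAz)) {
    # prefer a +g/-g pair among the near-line reflections
    pairIdx <- nearU[1:2]
    for (i in nearU) for (j in nearU) {
      if (i < j && sqrt(sum((gv[[i]]@k + gv[[j]]@k)^2)) < 2 * clusterTol)
        pairIdx <- c(i, j)
    }
    hand <- tryCatch(
      as.character(screwHandedness(vdfs[pairIdx], line)),
      error = function(e) "undetermined")
  }
  if (hand != "undetermined" && chr@label %in% c("screw", "mixed"))
    chr@handedness <- hand
  match <- slip <- NULL
  if (!is.null(cell) && !is.null(zone) && !is.na(bAz)) {
    match <- matchBurgers(bAz, cell, zone)
    if (isTRUE(attr(match, "matched"))) {
      bBest <- as.integer(match[1, c("u", "v", "w")])
      slip <- assignSlipSystem(bBest, line, zone, cell)
    } else qc <- c(qc, "no lattice direction matched the fitted azimuth")
  }
  list(gvectors = gv, vdfs = vdfs, flaggedRows = flagged, profile = profile,
       fit = fit, bAzimuth = bAz, invisibility = inv, character = chr,
       handedness = hand, match = match, slip = slip, qc = qc)
}

#' Polar plot of a displacement profile with its fit
#'
#' Measured |displacement| versus azimuth as points (with error bars) on a
#' polar axis, with the fitted model curve overlaid, mirroring the
#' conventional presentation of bend-contour displacement lobes.
#'
#' @param profile a [DisplacementProfile-class].
#' @param fit optional [BurgersFit-class] to overlay.
#' @return a ggplot object.
#' @export
polarPlot <- function(profile, fit = NULL) {
  tab <- crossingTable(profile)
  tab <- tab[tab$usable, , drop = FALSE]
  tab$ad <- abs(tab$displacement)
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = phi, y = ad)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = pmax(ad - uncertainty, 0),
                                          ymax = ad + uncertainty),
                             colour = "blue", size = 0.3) +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 315, by = 45)) +
    ggplot2::labs(x = expression(phi ~ "(deg)"),
                  y = "|displacement| (nm)") +
    ggplot2::theme_minimal()
  if (!is.null(fit) && !fit@noDistortion) {
    cv <- data.frame(phi = seq(0, 360, by = 1))
    cv$d <- modelF(cv$phi, fit@ampA, fit@shapeB, fit@phaseC)
    p <- p + ggplot2::geom_line(data = cv, ggplot2::aes(x = phi, y = d),
                                colour = "red")
  }
  p
}
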