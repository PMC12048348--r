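# Bragg-disc detection (difference of Gaussians + local maxima), sub-pixel
# centre-of-mass refinement, scan-wide g-vector consolidation and virtual
# dark-field reconstruction.

#' Construct a diffraction vector
#'
#' @param kx,ky reciprocal coordinates in inverse Angstrom (y-up frame).
#' @param phi azimuth in degrees; computed from atan2(ky, kx) plus
#'   `rotationOffset` when omitted.
#' @param rotationOffset rotation correction added to the azimuth, degrees.
#' @param hkl optional integer Miller triple.
#' @param usable logical metrology flag.
#' @return a [GVector-class].
#' @export
gVector <- function(kx, ky, phi = NULL, rotationOffset = 0,
                    hkl = integer(), usable = TRUE) {
  if (is.null(phi)) phi <- .wrap360(.rad2deg(atan2(ky, kx)) + rotationOffset)
  methods::new("GVector", k = c(kx, ky), magnitude = sqrt(kx^2 + ky^2),
               phi = phi, hkl = as.integer(hkl), usable = usable)
}

# detector (row, col) of a GVector on a dataset
.gToPixel <- function(ds, g) {
  c(ds@beamCenter[1] - g@k[2] / ds@detectorCal,
    ds@beamCenter[2] + g@k[1] / ds@detectorCal)
}

# detector (row, col) -> k (kx, ky) in inverse Angstrom, y-up
.pixelToK <- function(ds, row, col) {
  cbind(kx = (col - ds@beamCenter[2]) * ds@detectorCal,
        ky = -(row - ds@beamCenter[1]) * ds@detectorCal)
}

#' Find Bragg-disc candidates in one pattern
#'
#' Difference-of-Gaussians band-pass (sigmaLow minus sigmaHigh blur)
#' followed by 3x3 local-maximum detection above a relative threshold,
#' excluding the region around the direct beam. Candidates are returned
#' sorted by descending DoG response; ties resolve by raster order.
#'
#' @param pattern centred, distortion-corrected 2D pattern.
#' @param sigmaLow,sigmaHigh DoG standard deviations in px
#'   (sigmaLow < sigmaHigh).
#' @param threshold relative threshold on the DoG response (fraction of
#'   the maximum response).
#' @param excludeCenter exclusion radius around the direct beam, px.
#' @param center beam (row, col); defaults to the geometric centre.
#' @return data.frame with columns row, col, response.
#' @export
findDiscs <- function(pattern, sigmaLow = 1.2, sigmaHigh = 3.6,
                      threshold = 0.1, excludeCenter = 0, center = NULL) {
  if (sigmaLow >= sigmaHigh) stop("sigmaLow must be < sigmaHigh")
  nr <- nrow(pattern); nc <- ncol(pattern)
  if (is.null(center)) center <- c((nr + 1) / 2, (nc + 1) / 2)
  dog <- .gaussBlur(pattern, sigmaLow) - .gaussBlur(pattern, sigmaHigh)
  # the direct-beam region is excluded BEFORE thresholding so the (far
  # brighter) central beam does not set the reference response
  if (excludeCenter > 0) {
    rr <- outer((seq_len(nr) - center[1])^2, (seq_len(nc) - center[2])^2, "+")
    dog[rr < excludeCenter^2] <- 0
  }
  mx <- max(dog)
  if (mx <= 0) return(data.frame(row = numeric(), col = numeric(),
                                 response = numeric()))
  # 3x3 local maxima, interior only
  inner <- dog[2:(nr - 1), 2:(nc - 1)]
  isMax <- inner >= threshold * mx
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    isMax <- isMax & (inner >= dog[2:(nr - 1) + dr, 2:(nc - 1) + dc])
  }
  idx <- which(isMax, arr.ind = TRUE)
  if (!nrow(idx)) return(data.frame(row = numeric(), col = numeric(),
                                    response = numeric()))
  row <- idx[, 1] + 1; col <- idx[, 2] + 1
  keep <- sqrt((row - center[1])^2 + (col - center[2])^2) >= excludeCenter
  row <- row[keep]; col <- col[keep]
  resp <- dog[cbind(row, col)]
  o <- order(-resp, row, col)
  data.frame(row = row[o], col = col[o], response = resp[o])
}

#' Refine a disc position by iterated centre of mass
#'
#' Intensity-weighted centroid inside a square window, re-centred on the
#' running estimate (window resampled bilinearly at sub-pixel positions),
#' iterated to convergence below 0.01 px or 20 iterations.
#'
#' @param pattern 2D pattern.
#' @param candidate numeric (row, col) starting coordinate.
#' @param window half-width of the square window, px.
#' @return numeric (row, col), sub-pixel.
#' @export
refineCOM <- function(pattern, candidate, window = 4) {
  nr <- nrow(pattern); nc <- ncol(pattern)
  if (any(candidate - window < 1) || candidate[1] + window > nr ||
      candidate[2] + window > nc)
    stop("refinement window extends outside the pattern")
  pos <- as.numeric(candidate)
  off <- expand.grid(dr = seq(-window, window, by = 0.5),
                     dc = seq(-window, window, by = 0.5))
  for (i in seq_len(20)) {
    v <- .bilinear(pattern, pos[1] + off$dr, pos[2] + off$dc)
    tot <- sum(v)
    if (tot <= 0 || max(v) == min(v))
      stop("refinement error: no intensity contrast in window")
    newPos <- c(pos[1] + sum(v * off$dr) / tot,
                pos[2] + sum(v * off$dc) / tot)
    step <- sqrt(sum((newPos - pos)^2))
    pos <- newPos
    if (step < 0.01) break
  }
  pos
}

#' Consolidate per-pattern discs into a scan-wide g-vector list
#'
#' Runs disc finding plus centre-of-mass refinement on a seeded random
#' subsample of patterns, clusters the detections greedily by detector
#' position (a detection joins the nearest existing cluster within
#' `clusterTol`, else founds a new one; clusters ordered by first
#' appearance), and converts cluster medians to [GVector-class]s with
#' rotation-corrected azimuths. Friedel (+g/-g) partners are linked by
#' index in the `friedel` attribute.
#'
#' @param ds a centred [Dataset4D-class].
#' @param sampleFraction fraction of patterns to sample (default 0.05).
#' @param clusterTol clustering tolerance in inverse Angstrom.
#' @param minPatternFraction clusters seen in fewer than this fraction of
#'   sampled patterns are dropped as noise.
#' @param seed RNG seed for the pattern subsample.
#' @param ... passed to [findDiscs()].
#' @return list of [GVector-class] (possibly empty, with a warning), with
#'   attribute `friedel` giving the index of each vector's -g partner (NA
#'   when unpaired).
#' @export
consolidateGVectors <- function(ds, sampleFraction = 0.05, clusterTol = 0.02,
                                minPatternFraction = 0.05, seed = 1L, ...) {
  stopifnot(is(ds, "Dataset4D"))
  d <- dim(ds@counts)
  npat <- d[1] * d[2]
  nS <- max(1L, ceiling(sampleFraction * npat))
  hadSeed <- exists(".Random.seed", envir = globalenv())
  if (hadSeed) oldSeed <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  sel <- sample.int(npat, nS)
  if (hadSeed) assign(".Random.seed", oldSeed, envir = globalenv())
  excl <- 0.06 / ds@detectorCal           # direct-beam exclusion, px
  centers <- NULL; counts <- integer(); sums <- NULL
  for (p in sel) {
    iy <- (p - 1) %% d[1] + 1; ix <- (p - 1) %/% d[1] + 1
    pat <- ds@counts[iy, ix, , ]
    cand <- findDiscs(pat, excludeCenter = excl, center = ds@beamCenter, ...)
    if (!nrow(cand)) next
    for (j in seq_len(nrow(cand))) {
      pos <- tryCatch(refineCOM(pat, c(cand$row[j], cand$col[j]),
                                window = max(3, round(
                                  0.5 * discDiameterReciprocal(ds@geometry) /
                                    ds@detectorCal))),
                      error = function(e) NULL)
      if (is.null(pos)) next
      kxy <- .pixelToK(ds, pos[1], pos[2])
      if (is.null(centers)) {
        centers <- matrix(kxy, 1); sums <- matrix(kxy, 1); counts <- 1L
      } else {
        dist <- sqrt(rowSums((centers - matrix(kxy, nrow(centers), 2,
                                               byrow = TRUE))^2))
        m <- which.min(dist)
        if (dist[m] <= clusterTol) {
          sums[m, ] <- sums[m, ] + kxy
          counts[m] <- counts[m] + 1L
          centers[m, ] <- sums[m, ] / counts[m]
        } else {
          centers <- rbind(centers, kxy); sums <- rbind(sums, kxy)
          counts <- c(counts, 1L)
        }
      }
    }
  }
  if (is.null(centers)) {
    warning("no discs found anywhere")
    out <- list(); attr(out, "friedel") <- integer(); return(out)
  }
  # two physical discs cannot sit closer than one disc diameter, so any
  # cluster pair within that radius is one reflection: merge, weighted by
  # detection counts (the dominant cluster pins the position)
  mergeRadius <- discDiameterReciprocal(ds@geometry)
  o <- order(-counts)
  centers <- centers[o, , drop = FALSE]; counts <- counts[o]
  i <- 1L
  while (i < nrow(centers)) {
    dist <- sqrt(rowSums((centers - matrix(centers[i, ], nrow(centers), 2,
                                           byrow = TRUE))^2))
    absorb <- which(dist <= mergeRadius & seq_along(dist) > i)
    if (length(absorb)) {
      wAll <- c(counts[i], counts[absorb])
      centers[i, ] <- colSums(rbind(centers[i, ], centers[absorb, ,
                                    drop = FALSE]) * wAll) / sum(wAll)
      counts[i] <- sum(wAll)
      centers <- centers[-absorb, , drop = FALSE]
      counts <- counts[-absorb]
    }
    i <- i + 1L
  }
  keep <- counts >= max(2, minPatternFraction * nS)
  if (!any(keep)) keep <- counts == max(counts)
  centers <- centers[keep, , drop = FALSE]
  gv <- lapply(seq_len(nrow(centers)), function(i)
    gVector(centers[i, 1], centers[i, 2],
            rotationOffset = ds@rotationOffset))
  # link +g / -g pairs
  fr <- rep(NA_integer_, length(gv))
  for (i in seq_along(gv)) {
    if (!is.na(fr[i])) next
    tgt <- -gv[[i]]@k
    for (j in seq_along(gv)) {
      if (j == i || !is.na(fr[j])) next
      if (sqrt(sum((gv[[j]]@k - tgt)^2)) <= clusterTol) {
        fr[i] <- j; fr[j] <- i; break
      }
    }
  }
  attr(gv, "friedel") <- fr
  gv
}

#' Virtual dark-field image for one diffraction vector
#'
#' At every probe position, integrates the counts inside a circular
#' aperture (pixel-centre membership) centred at the reflection.
#'
#' @param ds a centred [Dataset4D-class].
#' @param g a [GVector-class].
#' @param apertureRadius aperture radius in inverse Angstrom; the paper's
#'   working range is 0.016-0.026, default 0.02.
#' @return a [VDFImage-class].
#' @export
vdf <- function(ds, g, apertureRadius = 0.02) {
  stopifnot(is(ds, "Dataset4D"), is(g, "GVector"))
  if (g@magnitude <= apertureRadius)
    stop("aperture would include the direct beam")
  discDiam <- discDiameterReciprocal(ds@geometry)
  if (2 * apertureRadius > discDiam)
    warning(sprintf(
      "aperture diameter %.3g exceeds the disc diameter %.3g (overlap risk)",
      2 * apertureRadius, discDiam))
  d <- dim(ds@counts)
  pos <- .gToPixel(ds, g)
  rpx <- apertureRadius / ds@detectorCal
  rr <- outer((seq_len(d[3]) - pos[1])^2, (seq_len(d[4]) - pos[2])^2, "+")
  mask <- as.numeric(rr <= rpx^2)
  img <- .asPatternMatrix(ds) %*% mask
  methods::new("VDFImage", image = matrix(img, d[1], d[2]), g = g,
               apertureRadius = apertureRadius, scanStep = ds@scanStep)
}

#' Usability of a reflection for metrology
#'
#' A reflection qualifies when the 99th percentile of its VDF exceeds
#' `k` times the median background, i.e. the contour stands clearly above
#' the shot-noise floor.
#'
#' @param v a [VDFImage-class].
#' @param k intensity ratio threshold (default 5).
#' @return logical.
#' @export
vdfUsable <- function(v, k = 5) {
  stopifnot(is(v, "VDFImage"))
  q <- stats::quantile(v@image, c(0.5, 0.99), names = FALSE)
  q[2] > k * max(q[1], 1e-9) && q[2] > 5
}

#' Tabulate a g-vector list
#'
#' @param gvectors list of [GVector-class].
#' @return data.frame with columns kx, ky, magnitude, phi, h, k, l, usable.
#' @export
gVectorTable <- function(gvectors) {
  do.call(rbind, lapply(gvectors, function(g) {
    hkl <- if (length(g@hkl)) g@hkl else rep(NA_integer_, 3)
    data.frame(kx = g@k[1], ky = g@k[2], magnitude = g@magnitude,
               phi = g@phi, h = hkl[1], k = hkl[2], l = hkl[3],
               usable = g@usable)
  }))
}
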