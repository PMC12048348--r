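# Bend-contour metrology: centerline (ridge) tracing in VDF images,
# displacement measurement across a dislocation line, and flagging of
# mid-scan reorientation artifacts.

#' Construct a dislocation line
#'
#' @param points n x 2 matrix (or 2-column object) of (x, y) scan-frame
#'   coordinates in nm; point order defines the positive sense.
#' @param positiveSense +1 to follow point order, -1 to reverse.
#' @return a [DislocationLine-class].
#' @export
dislocationLine <- function(points, positiveSense = 1) {
  methods::new("DislocationLine", polyline = as.matrix(points),
               positiveSense = positiveSense)
}

#' Local line direction as an azimuth
#'
#' Azimuth (degrees, y-up, mod 180) of the dislocation line: of the chord
#' when `s` is omitted, else of the local segment at arc length `s` (nm).
#'
#' @param line a [DislocationLine-class].
#' @param s optional arc-length coordinate in nm.
#' @return azimuth in degrees, `[0, 180)`.
#' @export
lineAzimuth <- function(line, s = NULL) {
  p <- line@polyline
  if (is.null(s)) {
    d <- p[nrow(p), ] - p[1, ]
  } else {
    d <- .polylinePoint(p, s)$dir
  }
  .wrap180(.azimuthYUp(d[1], d[2]))
}

# Ridge tracer in pixel coordinates. img: intensity matrix (bg-subtracted
# values are used), startRC: (row, col), dir0: unit (d_row, d_col) or NULL.
# Returns per-cut centres, widths (px), centroid SEs (px) and a partial
# flag when the ridge was lost before leaving the image.
.traceRidge <- function(img, startRC, bg, dir0 = NULL, halfWidth = 12,
                        step = 1, maxSteps = 400, minFrac = 0.25,
                        mask = NULL) {
  nr <- nrow(img); nc <- ncol(img)
  valid <- matrix(1, nr, nc)
  # a 2 px rim is never trusted: edge-clipped smoothing bends the ridge
  valid[c(1:2, nr - 1, nr), ] <- 0
  valid[, c(1:2, nc - 1, nc)] <- 0
  if (!is.null(mask)) { img <- img * mask; valid <- valid * (mask > 0.5) }
  ref <- max(img) - bg
  if (ref <= 0) stop("trace error: image carries no intensity above background")
  sample_t <- seq(-halfWidth, halfWidth, by = 0.5)
  cut <- function(p, n) {
    r <- p[1] + sample_t * n[1]; c <- p[2] + sample_t * n[2]
    list(v = pmax(.bilinear(img, r, c) - bg, 0),
         ok = .bilinear(valid, r, c, fill = 0) > 0.99)
  }
  # initial direction: the ridge axis is the low-|curvature| eigenvector of
  # the local Hessian (the cross-ridge eigenvalue is strongly negative)
  if (is.null(dir0)) {
    if (.bilinear(img, startRC[1], startRC[2]) <= bg)
      stop("trace error: seed lies on background")
    h <- 2
    sA <- function(dr, dc) .bilinear(img, startRC[1] + dr, startRC[2] + dc)
    irr <- (sA(h, 0) - 2 * sA(0, 0) + sA(-h, 0)) / h^2
    icc <- (sA(0, h) - 2 * sA(0, 0) + sA(0, -h)) / h^2
    irc <- (sA(h, h) - sA(h, -h) - sA(-h, h) + sA(-h, -h)) / (4 * h^2)
    eg <- eigen(matrix(c(irr, irc, irc, icc), 2), symmetric = TRUE)
    dir0 <- eg$vectors[, which.max(eg$values)]
  }
  # contiguous half-max band around the cut maximum; NULL when the band is
  # clipped by the image edge or the mask (such cuts would bias the centroid)
  bandOf <- function(ct) {
    v <- ct$v
    vmax <- max(v)
    if (vmax <= 0) return(NULL)
    im <- which.max(v)
    band <- v >= vmax / 2
    lo <- im; while (lo > 1 && band[lo - 1]) lo <- lo - 1
    hi <- im; while (hi < length(v) && band[hi + 1]) hi <- hi + 1
    # one guard sample beyond the band: a band ending ON an invalid sample
    # is a truncated band, not a real half-max edge
    if (!all(ct$ok[max(lo - 1, 1):min(hi + 1, length(v))])) return(NULL)
    list(sel = lo:hi, vmax = vmax)
  }
  # land the start point on the ridge centre before stepping
  n0 <- c(-dir0[2], dir0[1])
  b0 <- bandOf(ct0 <- cut(startRC, n0))
  if (!is.null(b0)) {
    w0 <- ct0$v[b0$sel]; t0 <- sample_t[b0$sel]
    startRC <- startRC + (sum(w0 * t0) / sum(w0)) * n0
  }
  oneDirection <- function(p0, d) {
    pts <- NULL; widths <- ses <- numeric(); misses <- 0L; partial <- FALSE
    p <- p0
    for (i in seq_len(maxSteps)) {
      p <- p + step * d
      # stop short of the boundary: edge-clipped smoothing bends the ridge
      if (p[1] < 3 || p[1] > nr - 2 || p[2] < 3 || p[2] > nc - 2) break
      n <- c(-d[2], d[1])
      ct <- cut(p, n)
      b <- bandOf(ct)
      if (is.null(b) || b$vmax < minFrac * ref) {
        misses <- misses + 1L
        if (misses > 3L) { partial <- i < maxSteps / 4; break }
        next
      }
      misses <- 0L
      sel <- b$sel
      w <- ct$v[sel]; t <- sample_t[sel]
      tc <- sum(w * t) / sum(w)
      pNew <- p + tc * n
      se <- sqrt(sum(w * 0.5 * (t - tc)^2)) / sum(w * 0.5)
      dNew <- pNew - (if (is.null(pts)) p0 else pts[nrow(pts), ])
      nrm <- sqrt(sum(dNew^2))
      if (nrm > 1e-9) {
        dNew <- dNew / nrm
        if (sum(dNew * d) < 0) dNew <- -dNew
        d <- d + 0.5 * (dNew - d); d <- d / sqrt(sum(d^2))
      }
      pts <- rbind(pts, pNew)
      widths <- c(widths, (length(sel) - 1) * 0.5)
      ses <- c(ses, se)
      p <- pNew
    }
    list(pts = pts, widths = widths, ses = ses, partial = partial)
  }
  fwd <- oneDirection(startRC, dir0)
  bwd <- oneDirection(startRC, -dir0)
  pts <- rbind(if (!is.null(bwd$pts)) bwd$pts[rev(seq_len(nrow(bwd$pts))), ],
               matrix(startRC, 1), fwd$pts)
  if (is.null(pts) || nrow(pts) < 3)
    stop("trace error: ridge could not be followed from the seed")
  list(points = pts,
       widths = c(rev(bwd$widths), NA, fwd$widths),
       ses = c(rev(bwd$ses), NA, fwd$ses),
       partial = fwd$partial || bwd$partial)
}

#' Trace a bend-contour centerline
#'
#' Follows the ridge of the (Gaussian-smoothed) VDF image from a seed
#' point: successive cuts are taken perpendicular to the local contour
#' direction and the centerline point is the intensity-weighted centroid
#' over the full-width-half-maximum band of each cut. Stops when the cut
#' maximum stays below the background-referenced floor for more than three
#' consecutive cuts (flagged partial if that happens early) or when the
#' trace leaves the image.
#'
#' @param v a [VDFImage-class].
#' @param seedPoint (x, y) scan-frame coordinate in nm, on or near the
#'   contour.
#' @param smoothing Gaussian smoothing length in nm (default two scan px).
#' @return list with `polyline` (n x 2, nm), `widths` (FWHM per cut, nm),
#'   `ses` (centroid standard errors, nm) and `partial` flag.
#' @export
traceContour <- function(v, seedPoint, smoothing = 2 * v@scanStep) {
  stopifnot(is(v, "VDFImage"))
  st <- v@scanStep
  img <- .gaussBlur(v@image, smoothing / st)
  bg <- stats::median(img)
  startRC <- c(seedPoint[2] / st + 1, seedPoint[1] / st + 1)
  val <- .bilinear(img, startRC[1], startRC[2])
  if (val <= bg) stop("trace error: seed lies on background")
  tr <- .traceRidge(img, startRC, bg)
  list(polyline = cbind(x = (tr$points[, 2] - 1) * st,
                        y = (tr$points[, 1] - 1) * st),
       widths = tr$widths * st, ses = tr$ses * st, partial = tr$partial)
}

# Normalized (mask-aware) Gaussian smoothing: blur(img * mask) / blur(mask)
# keeps full amplitude up to the mask edge; `valid` marks pixels whose
# smoothing kernel lies mostly inside the mask.
.maskedSmooth <- function(img, mask, sigma) {
  den <- .gaussBlur(mask, sigma)
  sm <- .gaussBlur(img * mask, sigma) / pmax(den, 0.05)
  list(img = sm * (den > 0.05), valid = (den > 0.98) * mask)
}

# weighted total-least-squares line through (row, col) points;
# returns centroid, unit direction, perpendicular residuals and abscissae
.fitLine <- function(pts, w) {
  w <- w / sum(w)
  mu <- c(sum(pts[, 1] * w), sum(pts[, 2] * w))
  cv <- stats::cov.wt(pts, wt = w, method = "ML")$cov
  e <- eigen(cv, symmetric = TRUE)
  d <- e$vectors[, 1]
  # perpendicular residuals
  res <- (pts[, 1] - mu[1]) * d[2] - (pts[, 2] - mu[2]) * d[1]
  list(mu = mu, dir = d, res = res,
       t = (pts[, 1] - mu[1]) * d[1] + (pts[, 2] - mu[2]) * d[2])
}

# .fitLine with one outlier-trimming pass (3 x MAD on the perpendicular
# residuals, with a half-pixel floor so exact traces are not decimated)
.fitLineRobust <- function(pts, w) {
  f <- .fitLine(pts, w)
  lim <- max(3 * stats::mad(f$res), 0.5)
  keep <- abs(f$res) <= lim
  if (sum(keep) >= 3 && any(!keep)) {
    f <- .fitLine(pts[keep, , drop = FALSE], w[keep])
    f$keep <- keep
  } else f$keep <- rep(TRUE, nrow(pts))
  f
}

#' Measure the bend-contour displacement at a dislocation line
#'
#' Implements the along-line displacement measurement: on each side of the
#' dislocation line the contour's intensity profile is sampled along lines
#' parallel to the dislocation line at increasing perpendicular offsets
#' (each side masked to its own half-plane before smoothing, so the other
#' side's contour segment cannot blend in; because every sampling line is
#' parallel to the mask boundary, the masked smoothing attenuates each cut
#' uniformly and the centroids are unbiased). The centroid of the
#' full-width-half-maximum band of each cut gives the contour middle's
#' along-line coordinate at that offset; a weighted straight-line fit of
#' coordinate versus offset, evaluated at offset zero, gives the contour
#' middle ON the line for that side. The displacement is the signed
#' distance along the line's positive sense from the near side's middle to
#' the far side's; its uncertainty combines both prediction errors and a
#' localization floor in quadrature.
#'
#' Crossings are marked unusable (with a reason) when either side's
#' profile cannot be followed or when the contour meets the line at less
#' than `minAngle` (inferred from the fitted offset slope).
#'
#' @param v a [VDFImage-class].
#' @param line a [DislocationLine-class] (nm).
#' @param seeds 2 x 2 matrix of (x, y) nm seed points, one per side of the
#'   line (row 1 = near side, row 2 = far side).
#' @param smoothing Gaussian smoothing in nm.
#' @param minAngle minimum usable crossing angle, degrees (default 15).
#' @param buffer half-width of the exclusion band along the line, scan px.
#' @param maxOffset largest perpendicular offset sampled, scan px.
#' @param systematicFloor centerline localization floor in scan pixels,
#'   added in quadrature to the statistical uncertainty; sub-pixel
#'   interpolation, smoothing and masking limit the accuracy of the
#'   crossing coordinate to about a quarter pixel even without noise.
#' @return a [ContourCrossing-class].
#' @export
measureDisplacement <- function(v, line, seeds, smoothing = 2 * v@scanStep,
                                minAngle = 15, buffer = 1.5,
                                maxOffset = 20, systematicFloor = 0.25) {
  stopifnot(is(v, "VDFImage"), is(line, "DislocationLine"))
  st <- v@scanStep
  nr <- nrow(v@image); nc <- ncol(v@image)
  polyPx <- (line@polyline / st) + 1   # (x, y) in px
  gr <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  fr <- .polylineFrame(polyPx, cbind(gr$col, gr$row))
  unusable <- function(reason) methods::new(
    "ContourCrossing", g = v@g, displacement = NA_real_,
    uncertainty = NA_real_, usable = FALSE, note = reason)
  Lpx <- .polylineLength(polyPx)
  sideFit <- function(seedNm) {
    seedPx <- seedNm / st + 1
    sf <- .polylineFrame(polyPx, matrix(seedPx, 1))
    sgn <- sign(sf$offset)
    if (sgn == 0) return(list(err = "seed lies on the dislocation line"))
    mask <- matrix(0, nr, nc)
    mask[cbind(gr$row, gr$col)] <- as.numeric(fr$offset * sgn > buffer)
    ms <- .maskedSmooth(v@image, mask, smoothing / st)
    img <- ms$img
    bg <- stats::median(img[mask > 0.5])
    ref <- max(img * (mask > 0.5)) - bg
    if (ref <= 0) return(list(err = "no intensity above background"))
    # sample I(s) along a line parallel to the polyline at offset delta;
    # the first cut spans the whole polyline, later windows track the
    # previous centroid
    halfWin <- 14
    cutAt <- function(delta, sCenter, wide = FALSE) {
      sVals <- if (wide) seq(-halfWin, Lpx + halfWin, by = 0.5)
               else sCenter + seq(-halfWin, halfWin, by = 0.5)
      pp <- vapply(sVals, function(s) {
        at <- .polylinePoint(polyPx, s)
        # extend beyond the polyline ends along the local direction
        base <- at$p + (s - min(max(s, 0), Lpx)) * at$dir
        nHat <- c(-at$dir[2], at$dir[1])     # offset normal (x, y)
        base + delta * nHat
      }, numeric(2))
      x <- pp[1, ]; y <- pp[2, ]
      inside <- x >= 3 & x <= nc - 2 & y >= 3 & y <= nr - 2
      vals <- pmax(.bilinear(img, y, x) - bg, 0)
      vals[!inside] <- 0
      list(v = vals, ok = inside, s = sVals)
    }
    # centroid of the half-max band at (or, for a wide cut, nearest to)
    # the reference coordinate sRef
    centroid <- function(ct, sRef = NULL) {
      vmax <- max(ct$v)
      if (vmax <= 0) return(NULL)
      im <- if (is.null(sRef)) which.max(ct$v) else {
        cand <- which(ct$v >= vmax / 2)
        if (!length(cand)) return(NULL)
        cand[which.min(abs(ct$s[cand] - sRef))]
      }
      band <- ct$v >= ct$v[im] / 2
      lo <- im; while (lo > 1 && band[lo - 1]) lo <- lo - 1
      hi <- im; while (hi < length(ct$v) && band[hi + 1]) hi <- hi + 1
      # guard one full band width beyond the band: a peak whose tail is
      # clipped by the image edge yields a surviving but displaced band
      g <- min(hi - lo + 2L, 8L)
      if (!all(ct$ok[max(lo - g, 1):min(hi + g, length(ct$v))]))
        return(NULL)
      w <- ct$v[lo:hi]; s <- ct$s[lo:hi]
      sc <- sum(w * s) / sum(w)
      list(s = sc, vmax = max(w), width = (hi - lo) * 0.5,
           se = sqrt(sum(w * 0.5 * (s - sc)^2)) / sum(w * 0.5))
    }
    # start the cuts 2.5 smoothing-sigmas clear of the exclusion band: the
    # kernel-displacement correction below is first-order and degrades for
    # cuts hugging the boundary
    deltas <- sgn * seq(buffer + 2.5 * smoothing / st, maxOffset, by = 1)
    # locate the contour on the full-length first cut, nearest the seed
    first <- centroid(cutAt(deltas[1], 0, wide = TRUE), sRef = sf$s)
    if (is.null(first) || first$vmax < 0.25 * ref)
      return(list(err = "contour not found near the seed"))
    sCur <- first$s
    out <- NULL
    for (delta in deltas) {
      ct <- cutAt(delta, sCur)
      cen <- centroid(ct)
      if (is.null(cen) || cen$vmax < 0.25 * ref) {
        if (!is.null(out) && nrow(out) >= 3) break else next
      }
      # effective offset of the cut: the mask-restricted smoothing kernel
      # probes, on average, a point displaced away from the boundary by
      # the truncated-Gaussian mean sigma * phi(z) / Phi(z)
      sigSm <- smoothing / st
      z <- (abs(delta) - buffer) / max(sigSm, 1e-6)
      deltaEff <- delta + sgn * sigSm * stats::dnorm(z) / stats::pnorm(z)
      out <- rbind(out, c(delta = deltaEff, s = cen$s, se = cen$se,
                          width = cen$width))
      sCur <- cen$s
    }
    if (is.null(out) || nrow(out) < 3)
      return(list(err = "contour profile could not be followed"))
    w <- 1 / pmax(out[, "se"], 1e-2)^2
    # weighted straight line s(delta), one outlier-trimming pass
    fitLin <- function(d, s, w) {
      W <- sum(w); db <- sum(w * d) / W; sb <- sum(w * s) / W
      Sdd <- sum(w * (d - db)^2)
      b <- if (Sdd > 0) sum(w * (d - db) * (s - sb)) / Sdd else 0
      a <- sb - b * db
      list(a = a, b = b, res = s - a - b * d, db = db, Sdd = Sdd, W = W)
    }
    f <- fitLin(out[, "delta"], out[, "s"], w)
    lim <- max(3 * stats::mad(f$res), 0.5)
    keep <- abs(f$res) <= lim
    if (sum(keep) >= 3 && any(!keep)) {
      out <- out[keep, , drop = FALSE]; w <- w[keep]
      f <- fitLin(out[, "delta"], out[, "s"], w)
    }
    n <- nrow(out)
    sig2 <- sum(w * f$res^2) / (f$W * max(n - 2, 1) / n)
    seIntercept <- sqrt(sig2 / n * (1 + f$db^2 * n /
                                      max(f$Sdd / mean(w), 1e-9)))
    list(s0 = f$a, slope = f$b,
         se = max(seIntercept, stats::median(out[, "se"]) / sqrt(n)),
         angle = .rad2deg(atan2(1, abs(f$b))),
         width = stats::median(out[, "width"]))
  }
  s1 <- sideFit(as.numeric(seeds[1, ]))
  if (!is.null(s1$err)) return(unusable(paste("near side:", s1$err)))
  s2 <- sideFit(as.numeric(seeds[2, ]))
  if (!is.null(s2$err)) return(unusable(paste("far side:", s2$err)))
  ang <- min(s1$angle, s2$angle)
  if (ang < minAngle)
    return(unusable(sprintf("crossing angle %.1f deg below %g deg", ang,
                            minAngle)))
  disp <- (s2$s0 - s1$s0) * st * line@positiveSense
  unc <- st * sqrt(s1$se^2 + s2$se^2 + systematicFloor^2)
  methods::new("ContourCrossing", g = v@g, displacement = disp,
               uncertainty = max(unc, 1e-6), usable = TRUE,
               contourWidth = mean(c(s1$width, s2$width)) * st *
                 sin(.deg2rad(ang)), note = "")
}

# one-dimensional cross-correlation shift of a relative to b (circular FFT,
# parabolic sub-sample refinement)
.xcorr1Shift <- function(a, b) {
  n <- length(a)
  a <- a - mean(a); b <- b - mean(b)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  cc <- Re(stats::fft(stats::fft(a * w) * Conj(stats::fft(b * w)),
                      inverse = TRUE)) / n
  p <- which.max(cc)
  wrap <- function(i) ((i - 1) %% n) + 1
  cm <- cc[wrap(p - 1)]; c0 <- cc[p]; cp <- cc[wrap(p + 1)]
  den <- cm - 2 * c0 + cp
  frac <- if (den >= 0) 0 else max(-0.5, min(0.5, 0.5 * (cm - cp) / den))
  s <- p - 1 + frac
  if (s > n / 2) s <- s - n
  s
}

#' Flag mid-scan reorientation artifacts
#'
#' Slight stage or beam reorientation during rastering shifts the bend
#' contours in every VDF at once; a real dislocation displaces contours
#' only in the reflections with g.B != 0. Rows where the row-to-row
#' contour shift (median-detrended cross-correlation between consecutive
#' scan rows) jumps beyond `threshold` pixels in at least `fraction` of
#' the VDFs are flagged for exclusion from metrology.
#'
#' @param vdfs list of at least three [VDFImage-class] objects.
#' @param threshold jump threshold in scan px (default 1.5).
#' @param fraction minimum fraction of VDFs that must show the jump.
#' @return integer vector of flagged scan rows (possibly empty).
#' @export
detectUniformShift <- function(vdfs, threshold = 1.5, fraction = 0.9) {
  if (length(vdfs) < 3)
    stop("insufficient evidence: at least 3 usable VDFs are required")
  stopifnot(all(vapply(vdfs, is, TRUE, "VDFImage")))
  nr <- nrow(vdfs[[1]]@image)
  jumps <- sapply(vdfs, function(v) {
    # smooth along each row only: cross-row smoothing would smear a
    # single-row jump over several rows, each below threshold
    img <- v@image %*% t(.gaussMat(ncol(v@image), 1))
    sh <- vapply(seq_len(nr - 1), function(r)
      .xcorr1Shift(img[r + 1, ], img[r, ]), 0)
    sh - stats::median(sh)
  })
  hit <- abs(jumps) > threshold
  rows <- which(rowMeans(hit) >= fraction) + 1L
  as.integer(rows)
}

#' Assemble a displacement profile
#'
#' Collects per-g crossings into a [DisplacementProfile-class]; unusable
#' crossings are retained (for reporting) but excluded from fitting, and
#' duplicate g vectors are rejected.
#'
#' @param crossings list of [ContourCrossing-class] objects.
#' @param phiConvention free-text azimuth convention note.
#' @return a [DisplacementProfile-class].
#' @export
buildProfile <- function(crossings,
                         phiConvention = "detector frame, rotation-corrected, y-up") {
  if (!length(crossings) || !any(vapply(crossings, slot, TRUE, "usable")))
    stop("empty profile: no usable crossings")
  kk <- t(vapply(crossings, function(cr) cr@g@k, numeric(2)))
  if (anyDuplicated(round(kk, 9)))
    stop("duplicate GVector in profile")
  methods::new("DisplacementProfile", crossings = crossings,
               phiConvention = phiConvention)
}
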