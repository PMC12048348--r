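# Internal numerical helpers: angle arithmetic, interpolation, separable
# Gaussian blur, FFT cross-correlation and polyline geometry.

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

# wrap into [0, 360)
.wrap360 <- function(x) ((x %% 360) + 360) %% 360

# wrap into [0, 180)
.wrap180 <- function(x) ((x %% 180) + 180) %% 180

# smallest signed difference a - b on a modulus-180 circle, in (-90, 90]
.angDiff180 <- function(a, b) {
  d <- .wrap180(a - b)
  ifelse(d > 90, d - 180, d)
}

# acute angle between two azimuths (directions mod 180), in [0, 90]
.acuteAngle <- function(a, b) abs(.angDiff180(a, b))

# azimuth (deg, y-up) of displacement (dx, dy) with dy in storage (down) sense
.azimuthYUp <- function(dx, dy) .wrap360(.rad2deg(atan2(-dy, dx)))

# unit direction vector (dx, dy_down) of a y-up azimuth in degrees
.dirVec <- function(azDeg) c(cos(.deg2rad(azDeg)), -sin(.deg2rad(azDeg)))

# Bilinear sampling of matrix `img` at fractional (row, col); vectors ok.
# Out-of-bounds samples return `fill`.
.bilinear <- function(img, row, col, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(row); c0 <- floor(col)
  fr <- row - r0; fc <- col - c0
  ok <- r0 >= 1 & c0 >= 1 & r0 <= nr - 1 & c0 <= nc - 1
  # clamp exact upper edge
  edge <- row >= 1 & col >= 1 & row <= nr & col <= nc & !ok
  out <- rep(fill, length(row))
  if (any(ok)) {
    i00 <- cbind(r0[ok], c0[ok])
    out[ok] <- img[i00] * (1 - fr[ok]) * (1 - fc[ok]) +
      img[cbind(r0[ok] + 1, c0[ok])] * fr[ok] * (1 - fc[ok]) +
      img[cbind(r0[ok], c0[ok] + 1)] * (1 - fr[ok]) * fc[ok] +
      img[cbind(r0[ok] + 1, c0[ok] + 1)] * fr[ok] * fc[ok]
  }
  if (any(edge))
    out[edge] <- img[cbind(pmin(pmax(round(row[edge]), 1), nr),
                           pmin(pmax(round(col[edge]), 1), nc))]
  out
}

# Row-normalized 1D Gaussian smoothing matrix with reflected-edge weights:
# blur(img) = K_r %*% img %*% t(K_c).
.gaussMat <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  idx <- seq_len(n)
  K <- exp(-outer(idx, idx, "-")^2 / (2 * sigma^2))
  K[K < 1e-12] <- 0
  K / rowSums(K)
}

# Separable Gaussian blur with edge renormalization.
.gaussBlur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  .gaussMat(nrow(img), sigma) %*% img %*% t(.gaussMat(ncol(img), sigma))
}

# 2D Hann window, used to apodize edges before FFT cross-correlation.
.hann2 <- function(nr, nc) {
  wr <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nr) - 1) / (nr - 1))
  wc <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nc) - 1) / (nc - 1))
  outer(wr, wc)
}

# Cross-correlation (circular, via FFT) of img against template; returns
# the shift (d_row, d_col) maximizing the correlation, sub-pixel by
# parabolic interpolation, plus the peak significance (peak / rms).
.xcorrShift <- function(img, template, apodize = TRUE) {
  nr <- nrow(img); nc <- ncol(img)
  a <- img - mean(img); b <- template - mean(template)
  if (apodize) { w <- .hann2(nr, nc); a <- a * w; b <- b * w }
  X <- stats::fft(a) * Conj(stats::fft(b))
  cc <- Re(stats::fft(X, inverse = TRUE)) / (nr * nc)
  pk <- which.max(cc)
  pr <- (pk - 1) %% nr + 1
  pc <- (pk - 1) %/% nr + 1
  # parabolic sub-pixel refinement on the circular grid
  sub <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (den >= 0) 0 else max(-0.5, min(0.5, 0.5 * (cm - cp) / den))
  }
  wrap <- function(i, n) ((i - 1) %% n) + 1
  dr <- sub(cc[wrap(pr - 1, nr), pc], cc[pr, pc], cc[wrap(pr + 1, nr), pc])
  dc <- sub(cc[pr, wrap(pc - 1, nc)], cc[pr, pc], cc[pr, wrap(pc + 1, nc)])
  sr <- pr - 1 + dr; sc <- pc - 1 + dc
  if (sr > nr / 2) sr <- sr - nr
  if (sc > nc / 2) sc <- sc - nc
  sig <- cc[pr, pc] / (stats::sd(cc) + .Machine$double.eps)
  list(shift = c(sr, sc), significance = sig)
}

# Sub-pixel image translation by (d_row, d_col) via the Fourier shift
# theorem (content moves BY the shift; periodic wrap at edges).
.fourierShift <- function(img, dr, dc) {
  nr <- nrow(img); nc <- ncol(img)
  fr <- c(0:floor(nr / 2), -(ceiling(nr / 2) - 1):-1)[1:nr] / nr
  fc <- c(0:floor(nc / 2), -(ceiling(nc / 2) - 1):-1)[1:nc] / nc
  if (nr %% 2 == 0) fr[nr / 2 + 1] <- abs(fr[nr / 2 + 1])
  if (nc %% 2 == 0) fc[nc / 2 + 1] <- abs(fc[nc / 2 + 1])
  ph <- exp(-2i * pi * (outer(fr * dr, fc * dc, "+")))
  Re(stats::fft(stats::fft(img) * ph, inverse = TRUE)) / (nr * nc)
}

# Undo an elliptical distortion x_detector = A x_true (about a center, in
# (row, col) px) by pulling each corrected pixel from its distorted
# position: out(x) = img(center + A (x - center)).
.affineResample <- function(img, affine, center) {
  nr <- nrow(img); nc <- ncol(img)
  gr <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  d <- cbind(gr$row - center[1], gr$col - center[2]) %*% t(affine)
  matrix(.bilinear(img, d[, 1] + center[1], d[, 2] + center[2]),
         nr, nc)
}

## ---- polyline geometry (scan frame, points are (x, y) in nm) ----

# Arc-length coordinate and signed perpendicular offset of points relative
# to a polyline. Side sign: positive where the point lies to the LEFT of
# the walking direction in the y-down storage frame (i.e. cross(d, v) > 0
# with cross = dx*vy - dy*vx). First/last segments are extended.
.polylineFrame <- function(poly, pts) {
  nseg <- nrow(poly) - 1L
  segd <- diff(poly)
  seglen <- sqrt(rowSums(segd^2))
  cum <- c(0, cumsum(seglen))
  n <- nrow(pts)
  bestS <- bestOff <- bestDist <- rep(NA_real_, n)
  for (i in seq_len(nseg)) {
    p0 <- poly[i, ]; d <- segd[i, ] / seglen[i]
    v1 <- pts[, 1] - p0[1]; v2 <- pts[, 2] - p0[2]
    t <- v1 * d[1] + v2 * d[2]
    tc <- pmin(pmax(t, if (i == 1) -Inf else 0),
               if (i == nseg) Inf else seglen[i])
    off <- d[1] * v2 - d[2] * v1           # signed perpendicular offset
    dx <- v1 - tc * d[1]; dy <- v2 - tc * d[2]
    dist <- sqrt(dx^2 + dy^2)
    upd <- is.na(bestDist) | dist < bestDist
    bestDist[upd] <- dist[upd]
    bestS[upd] <- cum[i] + tc[upd]
    bestOff[upd] <- off[upd]
  }
  list(s = bestS, offset = bestOff, dist = bestDist)
}

# Intersection of an infinite line (point q, unit direction e) with a
# polyline (first/last segments extended). Returns the polyline arc-length
# coordinate s and the crossing angle (deg, in (0, 90]).
.linePolylineIntersect <- function(poly, q, e) {
  nseg <- nrow(poly) - 1L
  segd <- diff(poly)
  seglen <- sqrt(rowSums(segd^2))
  cum <- c(0, cumsum(seglen))
  for (i in seq_len(nseg)) {
    p0 <- poly[i, ]; d <- segd[i, ] / seglen[i]
    den <- d[1] * e[2] - d[2] * e[1]
    if (abs(den) < 1e-12) next
    w <- q - p0
    t <- (w[1] * e[2] - w[2] * e[1]) / den   # along polyline segment
    lo <- if (i == 1) -Inf else 0
    hi <- if (i == nseg) Inf else seglen[i]
    if (t >= lo && t <= hi) {
      ang <- .acuteAngle(.azimuthYUp(d[1], d[2]), .azimuthYUp(e[1], e[2]))
      return(list(s = cum[i] + t, angle = 90 - abs(90 - max(ang, 1e-9))))
    }
  }
  NULL
}

# Total length of a polyline (nm).
.polylineLength <- function(poly) sum(sqrt(rowSums(diff(poly)^2)))

# Point on polyline at arc-length s (clamped), plus local unit direction.
.polylinePoint <- function(poly, s) {
  segd <- diff(poly)
  seglen <- sqrt(rowSums(segd^2))
  cum <- c(0, cumsum(seglen))
  s <- min(max(s, 0), cum[length(cum)])
  i <- max(1L, findInterval(s, cum, rightmost.closed = TRUE))
  i <- min(i, nrow(poly) - 1L)
  d <- segd[i, ] / seglen[i]
  list(p = poly[i, ] + (s - cum[i]) * d, dir = d)
}
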