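# Unit-cell arithmetic: metric tensors, d-spacings, zone-axis projection,
# azimuth -> lattice-direction matching, geometry-only indexing assistance,
# and dislocation-density bookkeeping.

#' Construct a unit cell
#'
#' @param a,b,c cell lengths in Angstrom.
#' @param alpha,beta,gamma cell angles in degrees.
#' @param label free-text provenance label.
#' @return a [UnitCell-class].
#' @export
unitCell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90, label = "") {
  methods::new("UnitCell", a = a, b = b, c = c, alpha = alpha, beta = beta,
               gamma = gamma, label = label)
}

#' Unit-cell volume
#'
#' @param cell a [UnitCell-class].
#' @return volume in cubic Angstrom.
#' @export
cellVolume <- function(cell) {
  ca <- cos(.deg2rad(cell@alpha)); cb <- cos(.deg2rad(cell@beta))
  cg <- cos(.deg2rad(cell@gamma))
  cell@a * cell@b * cell@c *
    sqrt(pmax(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg, 0))
}

# direct lattice basis vectors as rows of a 3x3 Cartesian matrix
.directBasis <- function(cell) {
  ca <- cos(.deg2rad(cell@alpha)); cb <- cos(.deg2rad(cell@beta))
  cg <- cos(.deg2rad(cell@gamma)); sg <- sin(.deg2rad(cell@gamma))
  v <- cellVolume(cell)
  rbind(a = c(cell@a, 0, 0),
        b = c(cell@b * cg, cell@b * sg, 0),
        c = c(cell@c * cb, cell@c * (ca - cb * cg) / sg,
              v / (cell@a * cell@b * sg)))
}

# reciprocal basis (rows a*, b*, c*), crystallographic convention a*.a = 1
.reciprocalBasis <- function(cell) t(solve(.directBasis(cell)))

# reciprocal metric tensor
.reciprocalMetric <- function(cell) {
  Ms <- .reciprocalBasis(cell)
  Ms %*% t(Ms)
}

#' Interplanar spacing
#'
#' d(hkl) = 1 / sqrt(h' G* h) with G* the reciprocal metric tensor.
#'
#' @param cell a [UnitCell-class].
#' @param hkl integer Miller triple (not all zero).
#' @return d-spacing in Angstrom.
#' @examples
#' dSpacing(builtinCell("p-terphenyl"), c(2, 1, 0))  # 3.28
#' @export
dSpacing <- function(cell, hkl) {
  stopifnot(is(cell, "UnitCell"), length(hkl) == 3)
  if (all(hkl == 0)) stop("hkl must not be (0,0,0)")
  Gs <- .reciprocalMetric(cell)
  1 / sqrt(as.numeric(t(hkl) %*% Gs %*% hkl))
}

# shared 2D orthonormal basis of a zone plane: e1 along the projection of
# the lowest-index in-zone reflection (ordered by index sum, then |g|,
# then lexicographic), e2 = n x e1 with n the real-space zone direction.
.zoneBasis <- function(cell, zone) {
  M <- .directBasis(cell)
  n <- as.numeric(zone %*% M)
  n <- n / sqrt(sum(n^2))
  Ms <- .reciprocalBasis(cell)
  idx <- as.matrix(expand.grid(h = -4:4, k = -4:4, l = -4:4))
  idx <- idx[rowSums(abs(idx)) > 0 & idx %*% zone == 0, , drop = FALSE]
  if (!nrow(idx)) stop("degenerate zone axis")
  gcart <- idx %*% Ms
  gm <- sqrt(rowSums(gcart^2))
  # canonical sign: first nonzero index positive
  firstSign <- apply(idx, 1, function(v) v[which(v != 0)[1]])
  keep <- firstSign > 0
  idx <- idx[keep, , drop = FALSE]; gcart <- gcart[keep, , drop = FALSE]
  gm <- gm[keep]
  o <- order(rowSums(abs(idx)), gm, idx[, 1], idx[, 2], idx[, 3])
  e1 <- gcart[o[1], ] / gm[o[1]]
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  list(n = n, e1 = e1, e2 = e2)
}

#' Reflections of a zone axis
#'
#' All hkl satisfying the zone law (h u + k v + l w = 0) with
#' |g| <= `gmax`, with 2D coordinates in the orthonormal zone-plane basis
#' shared with [projectDirection()]. Geometry only; structure factors and
#' extinctions are deliberately ignored.
#'
#' @param cell a [UnitCell-class].
#' @param zone integer zone-axis triple.
#' @param gmax maximum |g| in inverse Angstrom.
#' @return data.frame with columns h, k, l, gx, gy, magnitude, phi (deg).
#' @export
zoneGList <- function(cell, zone, gmax) {
  stopifnot(is(cell, "UnitCell"), gmax > 0)
  zb <- .zoneBasis(cell, zone)
  Ms <- .reciprocalBasis(cell)
  lim <- pmax(1L, ceiling(gmax / sqrt(rowSums(Ms^2))))
  idx <- as.matrix(expand.grid(h = -lim[1]:lim[1], k = -lim[2]:lim[2],
                               l = -lim[3]:lim[3]))
  idx <- idx[rowSums(abs(idx)) > 0 & idx %*% zone == 0, , drop = FALSE]
  gcart <- idx %*% Ms
  gm <- sqrt(rowSums(gcart^2))
  keep <- gm <= gmax
  idx <- idx[keep, , drop = FALSE]; gcart <- gcart[keep, , drop = FALSE]
  gm <- gm[keep]
  gx <- as.numeric(gcart %*% zb$e1); gy <- as.numeric(gcart %*% zb$e2)
  out <- data.frame(h = idx[, 1], k = idx[, 2], l = idx[, 3],
                    gx = gx, gy = gy, magnitude = gm,
                    phi = .wrap360(.rad2deg(atan2(gy, gx))))
  out[order(out$magnitude, out$h, out$k, out$l), , drop = FALSE]
}

#' Zone-plane azimuth of a lattice direction
#'
#' Projects the real-space vector u a + v b + w c onto the zone plane and
#' returns its azimuth in the same 2D basis as [zoneGList()], so crystal
#' and detector azimuths are commensurable after rotation calibration.
#'
#' @param cell a [UnitCell-class].
#' @param zone integer zone-axis triple.
#' @param uvw integer direction triple, not parallel to the zone axis.
#' @return azimuth in degrees `[0, 360)`.
#' @export
projectDirection <- function(cell, zone, uvw) {
  stopifnot(is(cell, "UnitCell"))
  zb <- .zoneBasis(cell, zone)
  t3 <- as.numeric(uvw %*% .directBasis(cell))
  tp <- t3 - sum(t3 * zb$n) * zb$n
  if (sqrt(sum(tp^2)) < 1e-9 * sqrt(sum(t3^2)))
    stop("undefined projection: direction is parallel to the zone axis")
  .wrap360(.rad2deg(atan2(sum(tp * zb$e2), sum(tp * zb$e1))))
}

#' Coprime candidate lattice directions
#'
#' All coprime integer triples [uvw] with |index| <= `maxIndex`
#' (canonical sign, no duplicates, no zero triple).
#'
#' @param maxIndex largest |index| (default 2).
#' @return matrix with columns u, v, w.
#' @export
latticeDirections <- function(maxIndex = 2) {
  idx <- as.matrix(expand.grid(u = -maxIndex:maxIndex, v = -maxIndex:maxIndex,
                               w = -maxIndex:maxIndex))
  idx <- idx[rowSums(abs(idx)) > 0, , drop = FALSE]
  red <- t(apply(idx, 1, .reduceTriple))
  unique(red)
}

#' Match a fitted Burgers azimuth to lattice directions
#'
#' Ranks candidate [uvw] directions by the acute difference (mod 180)
#' between their zone-plane projection and the fitted azimuth; ties break
#' by lower index sum, then shorter real-space length. Candidates within
#' `tol` are flagged matched; when none is, the ranking is still returned
#' with attribute `matched = FALSE` so the best near-miss is visible.
#'
#' @param fittedAzimuth Burgers azimuth from the fit, degrees.
#' @param cell a [UnitCell-class].
#' @param zone integer zone-axis triple.
#' @param candidates matrix of candidate uvw rows
#'   (default [latticeDirections()] with max index 2).
#' @param tol matching tolerance in degrees (default 3).
#' @return data.frame ranked by mismatch with columns u, v, w,
#'   projectedAzimuth, mismatch, matched; attribute `matched` says whether
#'   any candidate fell within `tol`.
#' @export
matchBurgers <- function(fittedAzimuth, cell, zone, candidates = NULL,
                         tol = 3) {
  if (is.na(fittedAzimuth)) stop("fit carried no resolvable distortion")
  if (is.null(candidates)) candidates <- latticeDirections(2)
  M <- .directBasis(cell)
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    uvw <- as.integer(candidates[i, ])
    pr <- tryCatch(projectDirection(cell, zone, uvw), error = function(e) NA)
    if (is.na(pr)) return(NULL)
    data.frame(u = uvw[1], v = uvw[2], w = uvw[3], projectedAzimuth = pr,
               mismatch = .acuteAngle(pr, fittedAzimuth),
               indexSum = sum(abs(uvw)),
               length = sqrt(sum((uvw %*% M)^2)))
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) stop("no projectable candidates")
  tab <- tab[order(tab$mismatch, tab$indexSum, tab$length), , drop = FALSE]
  tab$matched <- tab$mismatch <= tol
  rownames(tab) <- NULL
  attr(tab, "matched") <- any(tab$matched)
  tab
}

#' Rank candidate zone axes against observed reflections
#'
#' Rotation-invariant geometric scoring: for each candidate zone, the
#' simulated in-zone reflections are compared with the observed (|g|,
#' azimuth) list over all rotations suggested by magnitude-compatible
#' pairs; the rotation matching the most observed reflections (within
#' `magTol` and `angTol`) wins. Zones are ranked by matched fraction
#' (ties: fewer simulated reflections, i.e. the simpler pattern). A top
#' score below `floor` returns the ranking flagged "unindexed".
#'
#' @param gvectors list of at least three non-collinear [GVector-class].
#' @param cell a [UnitCell-class].
#' @param zones list or matrix of candidate zone-axis triples.
#' @param magTol magnitude tolerance, inverse Angstrom.
#' @param angTol azimuthal tolerance, degrees.
#' @param floor minimum matched fraction for an indexing call.
#' @return data.frame of zones ranked by score, with attributes
#'   `assignments` (per-g hkl for the best zone) and `indexed` (logical).
#' @export
indexAssist <- function(gvectors, cell, zones, magTol = 0.02, angTol = 3,
                        floor = 0.6) {
  stopifnot(length(gvectors) >= 3)
  obs <- gVectorTable(gvectors)
  az <- sort(.wrap180(obs$phi))
  if (max(az) - min(az) < 1e-6)
    stop("observed g vectors are collinear")
  if (is.matrix(zones)) zones <- lapply(seq_len(nrow(zones)), function(i) zones[i, ])
  gmax <- max(obs$magnitude) * 1.15
  scoreZone <- function(zone) {
    sim <- zoneGList(cell, zone, gmax)
    if (!nrow(sim)) return(list(score = 0, rot = NA, asg = NULL))
    bestScore <- 0; bestRot <- NA; bestAsg <- NULL
    cand <- unlist(lapply(seq_len(nrow(obs)), function(i) {
      j <- which(abs(sim$magnitude - obs$magnitude[i]) <= magTol)
      .wrap360(obs$phi[i] - sim$phi[j])
    }))
    for (rot in unique(round(cand, 2))) {
      asg <- rep(NA_integer_, nrow(obs))
      for (i in seq_len(nrow(obs))) {
        ok <- which(abs(sim$magnitude - obs$magnitude[i]) <= magTol)
        if (length(ok)) {
          dphi <- abs(((sim$phi[ok] + rot - obs$phi[i] + 180) %% 360) - 180)
          ok <- ok[dphi <= angTol]
          if (length(ok)) asg[i] <- ok[which.min(abs(sim$magnitude[ok] -
                                                       obs$magnitude[i]))]
        }
      }
      sc <- mean(!is.na(asg))
      if (sc > bestScore) { bestScore <- sc; bestRot <- rot; bestAsg <- asg }
    }
    list(score = bestScore, rot = bestRot, asg = bestAsg, nsim = nrow(sim),
         sim = sim)
  }
  res <- lapply(zones, scoreZone)
  tab <- data.frame(u = vapply(zones, `[`, 0, 1),
                    v = vapply(zones, `[`, 0, 2),
                    w = vapply(zones, `[`, 0, 3),
                    score = vapply(res, `[[`, 0, "score"),
                    rotation = vapply(res, function(r)
                      if (is.na(r$rot)) NA_real_ else r$rot, 0),
                    nReflections = vapply(res, function(r)
                      r$nsim %||% 0L, 0))
  o <- order(-tab$score, tab$nReflections)
  tab <- tab[o, , drop = FALSE]; res <- res[o]
  rownames(tab) <- NULL
  best <- res[[1]]
  asgTab <- NULL
  if (!is.null(best$asg)) {
    asgTab <- cbind(obs[, c("kx", "ky", "magnitude", "phi")],
                    best$sim[best$asg, c("h", "k", "l")])
  }
  attr(tab, "assignments") <- asgTab
  attr(tab, "indexed") <- tab$score[1] >= floor
  tab
}

#' Dislocation density from traced lines
#'
#' rho = total in-plane line length / (area x thickness), evaluated at
#' both thickness bounds.
#'
#' @param lines list of [DislocationLine-class] (polylines in nm).
#' @param area imaged area in square micrometres.
#' @param thickness numeric length-2 film thickness bounds in nm.
#' @return named numeric length-2, density in per square cm at the upper
#'   and lower thickness bound (ascending density).
#' @export
dislocationDensity <- function(lines, area, thickness) {
  stopifnot(area > 0, length(thickness) == 2, all(thickness > 0))
  if (!length(lines)) return(c(low = 0, high = 0))
  Lcm <- sum(vapply(lines, function(l) .polylineLength(l@polyline), 0)) * 1e-7
  Acm2 <- area * 1e-8
  tcm <- sort(thickness, decreasing = TRUE) * 1e-7
  c(low = Lcm / (Acm2 * tcm[1]), high = Lcm / (Acm2 * tcm[2]))
}

#' Maximum out-of-plane inclination of an in-film line
#'
#' arctan(thickness / projected length): a dislocation of the given
#' projected length confined to a film of the given thickness can rise at
#' most this many degrees out of plane.
#'
#' @param length projected line length in micrometres.
#' @param thickness film thickness in nm.
#' @return inclination bound in degrees.
#' @examples
#' outOfPlaneBound(2, 100)   # ~2.86 deg: predominantly in plane
#' @export
outOfPlaneBound <- function(length, thickness) {
  stopifnot(length > 0, thickness >= 0)
  .rad2deg(atan2(thickness, length * 1000))
}

#' Read cell constants from a CIF file
#'
#' Minimal parser limited to the `_cell_length_*` and `_cell_angle_*`
#' items (standard uncertainties in parentheses are stripped); symmetry
#' and atomic content are ignored.
#'
#' @param path CIF file path.
#' @param label optional label (defaults to the file name).
#' @return a [UnitCell-class].
#' @export
readCellCIF <- function(path, label = basename(path)) {
  ln <- readLines(path, warn = FALSE)
  grab <- function(key) {
    hit <- grep(paste0("^\\s*", key, "\\b"), ln, value = TRUE)
    if (!length(hit)) stop("CIF lacks ", key)
    val <- sub(paste0("^\\s*", key, "\\s+"), "", hit[1])
    as.numeric(sub("\\(.*\\)", "", val))
  }
  unitCell(a = grab("_cell_length_a"), b = grab("_cell_length_b"),
           c = grab("_cell_length_c"), alpha = grab("_cell_angle_alpha"),
           beta = grab("_cell_angle_beta"), gamma = grab("_cell_angle_gamma"),
           label = label)
}

#' Bundled reference unit cells
#'
#' Cell constants transcribed from the published crystal structures of the
#' benchmark molecular crystals (monoclinic p-terphenyl and anthracene,
#' both P2_1/a; orthorhombic theophylline form II).
#'
#' @param name one of "p-terphenyl", "anthracene", "theophylline-II".
#' @return a [UnitCell-class].
#' @export
builtinCell <- function(name = c("p-terphenyl", "anthracene",
                                 "theophylline-II")) {
  name <- match.arg(name)
  switch(name,
    "p-terphenyl" = unitCell(8.106, 5.613, 13.613, beta = 92.02,
                             label = "p-terphenyl P2_1/a (CCDC 1269381)"),
    "anthracene" = unitCell(8.562, 6.038, 11.184, beta = 124.70,
                            label = "anthracene P2_1/a (CCDC 1103062)"),
    "theophylline-II" = unitCell(24.612, 3.8302, 8.5010,
                                 label = "theophylline form II Pna2_1 (CCDC 128707)"))
}
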