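# Shared fixture builders: all synthetic, generated in code at test time.

# Straight-contour VDF scene: a bend contour with normal azimuth
# `bendAz` (deg, y-up) crossing a dislocation line, displaced by `f` nm
# along the line on the far side. Gaussian cross-section of sigma `w` nm.
# Returns the VDFImage, the line, and the scene parameters.
contourScene <- function(f = 0, w = 20, bendAz = 30, lineAz = 30,
                         n = 64, st = 8, amp = 200, noiseSeed = NULL,
                         g = gVector(0.2, 0.1)) {
  dirv <- function(az) c(cos(az * pi / 180), -sin(az * pi / 180))
  u <- dirv(lineAz)
  nh <- dirv(bendAz)
  ctr <- c((n - 1) * st / 2, (n - 1) * st * 0.45)
  line <- dislocationLineAt(ctr, lineAz, 0.55 * (n - 1) * st)
  gx <- rep((seq_len(n) - 1) * st, each = n)
  gy <- rep((seq_len(n) - 1) * st, times = n)
  side <- u[1] * (gy - ctr[2]) - u[2] * (gx - ctr[1])
  aF <- ctr + f * u
  dN <- (gx - ctr[1]) * nh[1] + (gy - ctr[2]) * nh[2]
  dF <- (gx - aF[1]) * nh[1] + (gy - aF[2]) * nh[2]
  dp <- ifelse(side > 0, dF, dN)
  img <- matrix(amp * exp(-dp^2 / (2 * w^2)), n, n)
  if (!is.null(noiseSeed)) {
    set.seed(noiseSeed)
    img <- matrix(rpois(length(img), img), n, n)
  }
  list(vdf = methods::new("VDFImage", image = img, g = g,
                          apertureRadius = 0.02, scanStep = st),
       line = line, center = ctr, f = f)
}

# Tiny 4D dataset with Gaussian discs planted at fixed detector positions,
# constant across the scan (intensity `peak` per disc), plus optional
# Poisson noise. Detector (nd x nd), scan (ns x ns).
discStack <- function(ns = 8, nd = 32, cal = 0.012,
                      discs = data.frame(kx = c(0.2, -0.2, 0.1),
                                         ky = c(0.1, -0.1, -0.2)),
                      peak = 100, sigmaPx = 1.7, poissonSeed = NULL,
                      rotationOffset = 0) {
  bc <- c((nd + 1) / 2, (nd + 1) / 2)
  pat <- matrix(0, nd, nd)
  for (i in seq_len(nrow(discs))) {
    rc <- c(bc[1] - discs$ky[i] / cal, bc[2] + discs$kx[i] / cal)
    pat <- pat + peak * exp(-outer((seq_len(nd) - rc[1])^2,
                                   (seq_len(nd) - rc[2])^2, "+") /
                              (2 * sigmaPx^2))
  }
  pat <- pat + 3 * peak * exp(-outer((seq_len(nd) - bc[1])^2,
                                     (seq_len(nd) - bc[2])^2, "+") /
                                (2 * sigmaPx^2))
  cnt <- aperm(array(pat, c(nd, nd, ns, ns)), c(3, 4, 1, 2))
  if (!is.null(poissonSeed)) {
    set.seed(poissonSeed)
    cnt[] <- rpois(length(cnt), cnt)
  }
  dataset4D(cnt, scanStep = 8, detectorCal = cal,
            rotationOffset = rotationOffset)
}

# Displacement profile from explicit (phi, displacement, sigma) samples.
profileFrom <- function(phi, d, sig, mag = 0.25, usable = TRUE) {
  usable <- rep_len(usable, length(phi))
  crs <- lapply(seq_along(phi), function(i)
    methods::new("ContourCrossing",
                 g = gVector(mag * cos(phi[i] * pi / 180),
                             mag * sin(phi[i] * pi / 180), phi = phi[i]),
                 displacement = d[i], uncertainty = sig[i],
                 usable = usable[i]))
  buildProfile(crs)
}

# Noisy model profile with evenly spread azimuths (guaranteed span).
noisyProfile <- function(A, B, C, n = 16, noise = 0.05, seed = 1) {
  set.seed(seed)
  phi <- sort((seq(0, 360, length.out = n + 1)[-1] + runif(n, -10, 10)) %% 360)
  d0 <- modelF(phi, A, B, C)
  sig <- rep(noise * max(d0), n)
  profileFrom(phi, abs(d0 + rnorm(n, 0, sig)), sig)
}

expect_angle_close <- function(a, b, tol) {
  d <- ((a - b + 90) %% 180) - 90
  expect_lt(abs(d), tol)
}
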