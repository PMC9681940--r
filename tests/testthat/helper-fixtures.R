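# Shared fixtures, built lazily and cached for the test session.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

defaultLabelMap1mm <- function() {
  fixture("lm1", function() buildPhantomLabelMap(defaultPhantomSpec(), 1))
}

defaultLabelMap2mm <- function() {
  fixture("lm2", function() buildPhantomLabelMap(defaultPhantomSpec(), 2))
}

noiselessCT1mm <- function() {
  fixture("ct1", function()
    renderCT(defaultLabelMap1mm(), ctModel(noiseSigma = 0)))
}

noiselessSPECT <- function() {
  fixture("sp0", function()
    renderSPECT(defaultLabelMap1mm(), spectModel(poissonScale = 0)))
}

# A compact phantom (small FOV) for tests that need fine voxel grids.
# Sphere centres sit at generic (non-half-voxel) grid alignments.
smallSpec <- function(slnCenters = rbind(left = c(25.2, 30.4, 29.8),
                                         right = c(45.3, 30.7, 30.2))) {
  phantomSpec(
    slnLeftDiameter = 8, slnRightDiameter = 15,
    slnCenters = slnCenters,
    vesselPath = list(list(points = rbind(c(35, 45, 30), c(35, 35, 30)),
                           radius = 2)),
    bone = list(type = "box", lower = c(10, 50, 10), upper = c(60, 56, 50)),
    fiducials = rbind(c(10, 10, 10), c(60, 12, 12), c(12, 50, 14),
                      c(58, 48, 40)),
    fiducialRadius = 4,
    fieldOfView = c(70, 60, 60))
}

# Random blob mask on an n x n grid (deterministic given seed).
randomMask <- function(n = 64, npix = 50, seed = 1) {
  set.seed(seed)
  m <- matrix(FALSE, n, n)
  ctr <- round(runif(2, n / 4, 3 * n / 4))
  pts <- unique(cbind(
    pmax(1, pmin(n, round(rnorm(npix * 2, ctr[1], n / 10)))),
    pmax(1, pmin(n, round(rnorm(npix * 2, ctr[2], n / 10))))))
  m[pts[seq_len(min(npix, nrow(pts))), ]] <- TRUE
  m
}

# --- naive per-pixel counting oracles (independent of the package
# implementations; deliberately written as explicit loops) ---

naiveBarycenter <- function(m) {
  su <- 0; sv <- 0; k <- 0
  for (r in seq_len(nrow(m))) for (c in seq_len(ncol(m))) {
    if (m[r, c]) { su <- su + (c - 1); sv <- sv + (r - 1); k <- k + 1 }
  }
  c(su / k, sv / k)
}

naiveArea <- function(m) {
  k <- 0
  for (r in seq_len(nrow(m))) for (c in seq_len(ncol(m)))
    if (m[r, c]) k <- k + 1
  k
}

naiveCoverage <- function(m1, m2) {
  both <- 0; n2 <- 0
  for (r in seq_len(nrow(m2))) for (c in seq_len(ncol(m2))) {
    if (m2[r, c]) {
      n2 <- n2 + 1
      if (m1[r, c]) both <- both + 1
    }
  }
  both / n2
}

naiveRatio <- function(m1, m2) {
  b1 <- naiveBarycenter(m1); b2 <- naiveBarycenter(m2)
  sqrt(sum((b1 - b2)^2)) / sqrt(naiveArea(m1) / pi)
}

diceCoefficient <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
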