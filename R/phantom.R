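#' @include AllClasses.R volume.R
NULL

.LABEL_CODES <- c(background = 0L, bone = 1L, vessel = 2L,
                  sln_left = 3L, sln_right = 4L)
.FID_BASE <- 10L  # fiducial_k gets code 10 + k

# Deterministic per-stage seed derivation, kept inside 32-bit range.
.stageSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1000 + stage) %% 2147483647)
}

#' Default digital phantom geometry
#'
#' The digital twin of a pelvic SLN phantom: a radiopaque pelvis-like
#' arch (half-cylindrical shell), a tubular vessel tree mimicking the
#' iliac bifurcation, two fillable SLN spheres (8 mm left, 15 mm right)
#' placed at the vessel endpoints, and a calibration board of 8
#' spherical fiducials at two heights (non-coplanar, irregularly spaced
#' so the configuration has no symmetric self-matching). The world
#' frame is right-handed, axes aligned with the phantom board, units
#' mm, origin at the field-of-view corner.
#'
#' @param slnLeftDiameter,slnRightDiameter SLN sphere diameters, mm.
#' @param fieldOfView phantom extent, mm.
#' @return A [PhantomSpec-class].
#' @examples
#' spec <- defaultPhantomSpec()
#' spec
#' @export
defaultPhantomSpec <- function(slnLeftDiameter = 8, slnRightDiameter = 15,
                               fieldOfView = c(180, 140, 110)) {
  phantomSpec(
    slnLeftDiameter = slnLeftDiameter,
    slnRightDiameter = slnRightDiameter,
    slnCenters = rbind(left = c(60, 75, 55), right = c(120, 75, 55)),
    vesselPath = list(
      list(points = rbind(c(90, 120, 55), c(90, 92, 55)), radius = 3.5),
      list(points = rbind(c(90, 92, 55), c(64.5, 77, 55)), radius = 3.5),
      list(points = rbind(c(90, 92, 55), c(113, 78, 55)), radius = 3.5)),
    bone = list(type = "arch", center = c(90, 75, 50), outerRadius = 55,
                thickness = 10, axis = "y", range = c(35, 115), zMin = 50),
    fiducials = rbind(c(35, 35, 30), c(145, 40, 32), c(40, 110, 34),
                      c(140, 105, 40), c(65, 30, 44), c(115, 112, 46),
                      c(32, 72, 38), c(148, 70, 48)),
    fiducialRadius = 5,
    fieldOfView = fieldOfView)
}

#' @rdname defaultPhantomSpec
#' @param slnCenters 2x3 matrix of sphere centres (left row first).
#' @param vesselPath list of `list(points, radius)` tube segments.
#' @param bone parametric bone description (`type = "arch"` or `"box"`).
#' @param fiducials Kx3 matrix of fiducial centres (K >= 4).
#' @param fiducialRadius fiducial sphere radius, mm.
#' @export
phantomSpec <- function(slnLeftDiameter, slnRightDiameter, slnCenters,
                        vesselPath, bone, fiducials, fiducialRadius,
                        fieldOfView) {
  new("PhantomSpec", slnLeftDiameter = slnLeftDiameter,
      slnRightDiameter = slnRightDiameter, slnCenters = slnCenters,
      vesselPath = vesselPath, bone = bone, fiducials = fiducials,
      fiducialRadius = fiducialRadius, fieldOfView = fieldOfView)
}

#' Default modality models
#'
#' `ctModel` uses HU-like means with bone and fiducials far above the
#' contrast-filled SLNs, which in turn exceed vessel contrast and the
#' gelatin background, plus additive Gaussian noise. `spectModel`
#' carries activity only in the SLN spheres (nominal 12 activity units
#' standing for the 12 MBq/mL filling), a 10 mm FWHM Gaussian PSF,
#' 4.4 mm voxels, and scaled-Poisson counting noise; the acquisition
#' parameters of the emulated protocol (60 projections of 30 s, 128
#' matrix, OSEM 8 iterations x 8 subsets, photopeak/scatter windows)
#' are recorded as metadata only.
#'
#' @param voxelSize acquisition voxel size in mm (scalar or length 3).
#' @param noiseSigma CT additive Gaussian noise SD (HU-like units).
#' @param activity SPECT activity in the SLN spheres, activity units.
#' @param psfFwhm SPECT PSF full width at half maximum, mm.
#' @param poissonScale expected counts per activity unit (0 = no noise).
#' @return A [ModalityModel-class].
#' @export
ctModel <- function(voxelSize = 1, noiseSigma = 10) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3)
  new("ModalityModel", kind = "CT",
      tissueIntensities = c(background = 40, bone = 1200, vessel = 300,
                            sln_left = 600, sln_right = 600,
                            fiducial = 1500),
      psfFwhm = 0, noise = c(sigma = noiseSigma),
      voxelSize = as.numeric(voxelSize), meta = list())
}

#' @rdname ctModel
#' @export
spectModel <- function(voxelSize = 4.4, activity = 12, psfFwhm = 10,
                       poissonScale = 40) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3)
  new("ModalityModel", kind = "SPECT",
      tissueIntensities = c(background = 0, bone = 0, vessel = 0,
                            sln_left = activity, sln_right = activity,
                            fiducial = 0),
      psfFwhm = psfFwhm, noise = c(scale = poissonScale),
      voxelSize = as.numeric(voxelSize),
      meta = list(projections = 60, secondsPerProjection = 30,
                  matrixSize = 128,
                  reconstruction = "OSEM 8 iterations x 8 subsets",
                  photopeakWindow = "140.5 keV, 20% width",
                  scatterWindow = "120 keV, 10% width"))
}

# squared distance from points (N x 3) to a segment [a, b]
.segDist2 <- function(px, py, pz, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) {
    return((px - a[1])^2 + (py - a[2])^2 + (pz - a[3])^2)
  }
  t <- ((px - a[1]) * ab[1] + (py - a[2]) * ab[2] + (pz - a[3]) * ab[3]) / len2
  t <- pmin(1, pmax(0, t))
  (px - (a[1] + t * ab[1]))^2 + (py - (a[2] + t * ab[2]))^2 +
    (pz - (a[3] + t * ab[3]))^2
}

#' Voxelize the phantom into a LabelMap
#'
#' A voxel is labelled with a structure if its centre lies inside that
#' structure; overlaps are resolved with the fixed precedence
#' fiducial > SLN > vessel > bone > background. The grid covers the
#' spec's field of view, with voxel centres at `(i + 1/2) * voxelSize`.
#'
#' @param spec a valid [PhantomSpec-class].
#' @param voxelSize grid spacing in mm (scalar or length 3).
#' @return A [LabelMap-class] with labels background, bone, vessel,
#'   sln_left, sln_right and fiducial_1 ... fiducial_K.
#' @examples
#' lm <- buildPhantomLabelMap(defaultPhantomSpec(), voxelSize = 4)
#' table(voxelValues(lm))[c("3", "4")]  # two SLN labels, right larger
#' @export
buildPhantomLabelMap <- function(spec, voxelSize = 1) {
  validObject(spec)
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3)
  fov <- spec@fieldOfView
  dims <- pmax(1L, as.integer(round(fov / voxelSize)))
  xs <- (seq_len(dims[1]) - 0.5) * voxelSize[1]
  ys <- (seq_len(dims[2]) - 0.5) * voxelSize[2]
  zs <- (seq_len(dims[3]) - 0.5) * voxelSize[3]
  n <- prod(dims)
  px <- rep(xs, times = dims[2] * dims[3])
  py <- rep(rep(ys, each = dims[1]), times = dims[3])
  pz <- rep(zs, each = dims[1] * dims[2])

  lab <- integer(n)

  b <- spec@bone
  if (identical(b$type, "arch")) {
    rad2 <- (px - b$center[1])^2 + (pz - b$center[3])^2
    inBone <- rad2 <= b$outerRadius^2 &
      rad2 >= (b$outerRadius - b$thickness)^2 &
      pz >= b$zMin & py >= b$range[1] & py <= b$range[2]
  } else if (identical(b$type, "box")) {
    inBone <- px >= b$lower[1] & px <= b$upper[1] &
      py >= b$lower[2] & py <= b$upper[2] &
      pz >= b$lower[3] & pz <= b$upper[3]
  } else stop("unknown bone type: ", b$type)
  lab[inBone] <- .LABEL_CODES[["bone"]]

  for (seg in spec@vesselPath) {
    p <- seg$points
    for (i in seq_len(nrow(p) - 1)) {
      d2 <- .segDist2(px, py, pz, p[i, ], p[i + 1, ])
      lab[d2 <= seg$radius^2] <- .LABEL_CODES[["vessel"]]
    }
  }

  rads <- c(spec@slnLeftDiameter, spec@slnRightDiameter) / 2
  codes <- c(.LABEL_CODES[["sln_left"]], .LABEL_CODES[["sln_right"]])
  for (i in 1:2) {
    ctr <- spec@slnCenters[i, ]
    d2 <- (px - ctr[1])^2 + (py - ctr[2])^2 + (pz - ctr[3])^2
    sel <- d2 <= rads[i]^2
    if (!any(sel))
      stop("SLN sphere ", i, " contains no voxel centre at this voxel size")
    lab[sel] <- codes[i]
  }

  fidNames <- character(0)
  for (k in seq_len(nrow(spec@fiducials))) {
    ctr <- spec@fiducials[k, ]
    d2 <- (px - ctr[1])^2 + (py - ctr[2])^2 + (pz - ctr[3])^2
    lab[d2 <= spec@fiducialRadius^2] <- .FID_BASE + k
    fidNames <- c(fidNames, sprintf("fiducial_%d", k))
  }

  labels <- c(.LABEL_CODES,
              stats::setNames(.FID_BASE + seq_len(nrow(spec@fiducials)),
                              fidNames))
  vals <- array(as.numeric(lab), dims)
  new("LabelMap",
      volume3D(vals, voxelSize, origin = voxelSize / 2),
      labels = labels)
}

# Session grid for a render: same physical extent as the phantom FOV,
# axis-aligned in session-world coordinates and centred on the posed
# phantom (the scanner centres the object in its field of view).
.sessionGrid <- function(labelmap, voxelSize, pose) {
  fov <- dim(labelmap@values) * labelmap@spacing
  dims <- pmax(1L, as.integer(round(fov / voxelSize)))
  centre <- applyTransform(pose, labelmap@origin - labelmap@spacing / 2 + fov / 2)
  origin <- centre - fov / 2 + voxelSize / 2
  volume3D(array(0, dims), voxelSize, origin)
}

# intensity lookup table indexed by label code + 1
.intensityLUT <- function(labelmap, intensities) {
  codes <- labelmap@labels
  lut <- numeric(max(codes) + 1)
  for (nm in names(codes)) {
    key <- if (grepl("^fiducial_", nm)) "fiducial" else nm
    val <- intensities[[key]]
    if (is.null(val) || is.na(val)) val <- 0
    lut[codes[[nm]] + 1] <- val
  }
  lut
}

#' Simulate a CT-like acquisition of the phantom
#'
#' Resamples the label map onto the CT session grid after applying
#' `pose` (the phantom's position in the session; nearest-neighbour,
#' so each voxel takes its label's mean intensity exactly), then adds
#' seeded Gaussian noise. The session grid is centred on the posed
#' phantom. Bit-reproducible for a fixed seed.
#'
#' @param labelmap a [LabelMap-class] from [buildPhantomLabelMap()].
#' @param model a CT [ModalityModel-class].
#' @param pose a [RigidTransform-class] mapping phantom world to
#'   session world (default identity).
#' @param seed integer RNG seed for the noise.
#' @return A [Volume3D-class] on the session grid.
#' @export
renderCT <- function(labelmap, model, pose = identityTransform(), seed = 1) {
  if (model@kind != "CT") stop("model kind must be CT")
  grid <- .sessionGrid(labelmap, model@voxelSize, pose)
  labs <- resampleVolume(labelmap, pose, grid, "nearest",
                         fill = .LABEL_CODES[["background"]])
  lv <- labs@values
  for (code in c(.LABEL_CODES[["sln_left"]], .LABEL_CODES[["sln_right"]]))
    if (!any(lv == code))
      stop("pose moves an SLN outside the field of view")
  lut <- .intensityLUT(labelmap, model@tissueIntensities)
  vals <- lut[lv + 1]
  dim(vals) <- dim(lv)
  sigma <- model@noise[["sigma"]]
  if (sigma > 0) {
    set.seed(seed)
    vals <- vals + rnorm(length(vals), 0, sigma)
    dim(vals) <- dim(lv)
  }
  volume3D(vals, grid@spacing, grid@origin, grid@orientation)
}

#' Simulate a SPECT-like acquisition of the phantom
#'
#' Builds the activity map (hot SLN spheres) on the SPECT session grid
#' under `pose`, integrating each coarse voxel by `supersample`^3
#' sub-voxel samples of the label map (partial-volume behaviour at the
#' 4.4 mm default voxel), convolves with an isotropic Gaussian PSF of
#' FWHM `model@psfFwhm`, then applies seeded Poisson counting noise:
#' `rpois(activity * scale) / scale`. Deterministic for a fixed seed.
#'
#' @inheritParams renderCT
#' @param model a SPECT [ModalityModel-class].
#' @param supersample sub-voxel sampling factor per axis.
#' @return A [Volume3D-class] activity map on the session grid.
#' @export
renderSPECT <- function(labelmap, model, pose = identityTransform(),
                        seed = 1, supersample = 3L) {
  if (model@kind != "SPECT") stop("model kind must be SPECT")
  if (any(model@tissueIntensities < 0)) stop("negative activity")
  grid <- .sessionGrid(labelmap, model@voxelSize, pose)
  lut <- .intensityLUT(labelmap, model@tissueIntensities)
  A0 <- .worldToIndex(labelmap) %*% invertTransform(pose)@matrix %*%
    .indexToWorld(grid)
  odim <- dim(grid@values)
  acc <- numeric(prod(odim))
  offs <- (seq_len(supersample) - (supersample + 1) / 2) / supersample
  for (ox in offs) for (oy in offs) for (oz in offs) {
    A <- A0
    A[, 4] <- A0 %*% c(ox, oy, oz, 1)
    labs <- cpp_resample(as.numeric(labelmap@values), dim(labelmap@values),
                         odim, as.numeric(A), TRUE,
                         .LABEL_CODES[["background"]])
    acc <- acc + lut[labs + 1]
  }
  vals <- acc / length(offs)^3
  dim(vals) <- odim
  if (model@psfFwhm > 0) {
    sigmaVox <- model@psfFwhm / (2 * sqrt(2 * log(2))) / grid@spacing
    vals <- gaussianSmooth3D(vals, sigmaVox)
  }
  scale <- model@noise[["scale"]]
  if (scale > 0) {
    set.seed(seed)
    vals <- rpois(length(vals), pmax(0, vals) * scale) / scale
    dim(vals) <- odim
  }
  volume3D(vals, grid@spacing, grid@origin, grid@orientation)
}
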