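#' @include arfusion-package.R
NULL

.isNumericLen <- function(x, n) is.numeric(x) && length(x) == n && all(is.finite(x))

#' Volume3D: a 3D scalar grid in world millimetres
#'
#' A scalar voxel grid with spacing, origin and axis orientation. The
#' world coordinate of 0-based voxel index `i` (addressing the voxel
#' centre) is `origin + orientation %*% (spacing * i)`. The world frame
#' is right-handed with units of millimetres.
#'
#' @slot values numeric 3D array of voxel values.
#' @slot spacing numeric(3), strictly positive voxel size in mm.
#' @slot origin numeric(3), world position of voxel (0,0,0), mm.
#' @slot orientation 3x3 direction matrix, orthonormal with det +1.
#' @exportClass Volume3D
setClass("Volume3D", representation(
  values = "array", spacing = "numeric", origin = "numeric",
  orientation = "matrix"))

setValidity("Volume3D", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "'values' must be a 3D array")
  if (!.isNumericLen(object@spacing, 3) || any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 strictly positive numbers")
  if (!.isNumericLen(object@origin, 3))
    msg <- c(msg, "'origin' must be numeric(3)")
  o <- object@orientation
  if (!is.numeric(o) || !all(dim(o) == c(3, 3))) {
    msg <- c(msg, "'orientation' must be a 3x3 matrix")
  } else {
    if (max(abs(crossprod(o) - diag(3))) > 1e-8)
      msg <- c(msg, "'orientation' must be orthonormal")
    if (abs(det(o) - 1) > 1e-8)
      msg <- c(msg, "'orientation' must have determinant +1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Volume3D
#'
#' @param values numeric 3D array.
#' @param spacing voxel size in mm (scalar or length 3).
#' @param origin world coordinate of the first voxel centre, mm.
#' @param orientation 3x3 direction matrix (default identity).
#' @return A [Volume3D-class] object.
#' @examples
#' v <- volume3D(array(0, c(4, 4, 4)), spacing = 2)
#' spacing(v)
#' @export
volume3D <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     orientation = diag(3)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  new("Volume3D", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin), orientation = orientation)
}

#' LabelMap: integer-labelled segmentation grid
#'
#' A [Volume3D-class] whose voxel values are integer structure codes,
#' together with the name-to-code dictionary.
#'
#' @slot labels named integer vector mapping structure name to code;
#'   must contain "background".
#' @exportClass LabelMap
setClass("LabelMap", contains = "Volume3D",
         representation(labels = "integer"))

setValidity("LabelMap", function(object) {
  msg <- character()
  if (is.null(names(object@labels)) || anyDuplicated(names(object@labels)))
    msg <- c(msg, "'labels' must be uniquely named")
  if (!"background" %in% names(object@labels))
    msg <- c(msg, "'labels' must include 'background'")
  codes <- unique(as.vector(object@values))
  if (!all(codes %in% object@labels))
    msg <- c(msg, "voxel values outside the label dictionary")
  if (length(msg)) msg else TRUE
})

#' RigidTransform: 6-DOF rigid map as a 4x4 homogeneous matrix
#'
#' Represents a rigid (rotation + translation) map between world
#' coordinate frames. The convention throughout the package is that a
#' registration transform maps moving-volume world coordinates to
#' fixed-volume world coordinates.
#'
#' @slot matrix 4x4 homogeneous matrix; rotation block orthonormal with
#'   det +1, last row (0, 0, 0, 1).
#' @exportClass RigidTransform
setClass("RigidTransform", representation(matrix = "matrix"))

setValidity("RigidTransform", function(object) {
  m <- object@matrix
  msg <- character()
  if (!is.numeric(m) || !all(dim(m) == c(4, 4)) || !all(is.finite(m)))
    return("'matrix' must be a finite 4x4 matrix")
  R <- m[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    msg <- c(msg, "rotation block must be orthonormal")
  if (abs(det(R) - 1) > 1e-6)
    msg <- c(msg, "rotation block must have determinant +1 (no reflection)")
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 0)
    msg <- c(msg, "last row must be (0, 0, 0, 1)")
  if (length(msg)) msg else TRUE
})

#' PhantomSpec: geometry of the digital pelvic phantom
#'
#' Parametric description of the phantom: two SLN spheres (8 mm left,
#' 15 mm right by default), a tubular vessel tree mimicking the iliac
#' vessels, a radiopaque pelvis-like arch, and a calibration board of
#' at least 4 non-coplanar spherical fiducials. All coordinates are in
#' the phantom world frame (mm), origin at the field-of-view corner.
#'
#' @slot slnLeftDiameter,slnRightDiameter sphere diameters, mm.
#' @slot slnCenters 2x3 matrix of sphere centres, rows left then right.
#' @slot vesselPath list of segments, each `list(points = Nx3 matrix,
#'   radius = mm)`; voxels within `radius` of the polyline are vessel.
#' @slot bone parametric arch/box description (see [defaultPhantomSpec()]).
#' @slot fiducials Kx3 matrix (K >= 4) of fiducial sphere centres, mm.
#' @slot fiducialRadius fiducial sphere radius, mm.
#' @slot fieldOfView numeric(3) extent of the phantom volume, mm.
#' @exportClass PhantomSpec
setClass("PhantomSpec", representation(
  slnLeftDiameter = "numeric", slnRightDiameter = "numeric",
  slnCenters = "matrix", vesselPath = "list", bone = "list",
  fiducials = "matrix", fiducialRadius = "numeric",
  fieldOfView = "numeric"))

.insideFov <- function(lo, hi, fov) all(lo >= 0) && all(hi <= fov)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  fov <- object@fieldOfView
  if (!.isNumericLen(fov, 3) || any(fov <= 0))
    return("'fieldOfView' must be 3 positive numbers")
  if (length(object@slnLeftDiameter) != 1 || object@slnLeftDiameter <= 0 ||
      length(object@slnRightDiameter) != 1 || object@slnRightDiameter <= 0)
    msg <- c(msg, "SLN sphere diameters must be strictly positive")
  sc <- object@slnCenters
  if (!all(dim(sc) == c(2, 3))) {
    msg <- c(msg, "'slnCenters' must be a 2x3 matrix (left, right)")
  } else {
    if (!(sc[1, 1] < sc[2, 1]))
      msg <- c(msg, "left SLN centre must have strictly smaller first world coordinate than right")
    r <- c(object@slnLeftDiameter, object@slnRightDiameter) / 2
    for (i in 1:2)
      if (!.insideFov(sc[i, ] - r[i], sc[i, ] + r[i], fov))
        msg <- c(msg, sprintf("SLN sphere %d extends outside field_of_view", i))
  }
  fid <- object@fiducials
  if (nrow(fid) < 4) {
    msg <- c(msg, "at least 4 fiducials are required")
  } else {
    ctr <- sweep(fid, 2, colMeans(fid))
    if (qr(ctr)$rank < 3)
      msg <- c(msg, "fiducials must be non-collinear and non-coplanar")
    fr <- object@fiducialRadius
    if (!.insideFov(apply(fid, 2, min) - fr, apply(fid, 2, max) + fr, fov))
      msg <- c(msg, "a fiducial extends outside field_of_view")
  }
  for (seg in object@vesselPath) {
    p <- seg$points
    if (!.insideFov(apply(p, 2, min) - seg$radius,
                    apply(p, 2, max) + seg$radius, fov))
      msg <- c(msg, "vessel tube extends outside field_of_view")
  }
  b <- object@bone
  if (identical(b$type, "arch")) {
    lo <- c(b$center[1] - b$outerRadius, b$range[1], b$zMin)
    hi <- c(b$center[1] + b$outerRadius, b$range[2],
            b$center[3] + b$outerRadius)
    if (!.insideFov(lo, hi, fov))
      msg <- c(msg, "bone arch extends outside field_of_view")
  } else if (identical(b$type, "box")) {
    if (!.insideFov(b$lower, b$upper, fov))
      msg <- c(msg, "bone box extends outside field_of_view")
  }
  if (length(msg)) msg else TRUE
})

#' ModalityModel: imaging model for one acquisition arm
#'
#' Defines how a [LabelMap-class] is turned into a simulated image:
#' per-structure mean intensities, voxel size, the point-spread
#' function (SPECT only), and the noise model (additive Gaussian for
#' CT, scaled Poisson counting for SPECT).
#'
#' @slot kind "CT" or "SPECT".
#' @slot tissueIntensities named numeric: mean intensity per structure
#'   name (CT in HU-like units; SPECT in activity-like units).
#' @slot psfFwhm isotropic Gaussian PSF full width at half maximum, mm
#'   (SPECT; 0 disables blurring).
#' @slot noise named numeric: `sigma` (CT) or `scale` (SPECT counts per
#'   activity unit; 0 disables noise).
#' @slot voxelSize numeric(3) acquisition voxel size, mm.
#' @slot meta list of acquisition provenance recorded but not simulated.
#' @exportClass ModalityModel
setClass("ModalityModel", representation(
  kind = "character", tissueIntensities = "numeric", psfFwhm = "numeric",
  noise = "numeric", voxelSize = "numeric", meta = "list"))

setValidity("ModalityModel", function(object) {
  msg <- character()
  if (!object@kind %in% c("CT", "SPECT"))
    msg <- c(msg, "'kind' must be \"CT\" or \"SPECT\"")
  if (is.null(names(object@tissueIntensities)))
    msg <- c(msg, "'tissueIntensities' must be named by structure")
  if (object@psfFwhm < 0) msg <- c(msg, "'psfFwhm' must be >= 0")
  if (any(object@noise < 0)) msg <- c(msg, "noise parameters must be >= 0")
  if (!.isNumericLen(object@voxelSize, 3) || any(object@voxelSize <= 0))
    msg <- c(msg, "'voxelSize' must be 3 positive numbers")
  if (object@kind == "SPECT") {
    ti <- object@tissueIntensities
    hot <- names(ti)[ti > 0]
    if (!all(hot %in% c("sln_left", "sln_right", "background")))
      msg <- c(msg, "SPECT activity must be zero except SLNs (and optional low background)")
  }
  if (length(msg)) msg else TRUE
})

#' StructureSet: named binary masks with centroids and volumes
#'
#' The result of segmenting one volume: a named list of structures,
#' each with a binary mask on the source grid, a world-space centroid
#' (mm) and a volume (mm^3), plus the grid geometry shared by all
#' masks.
#'
#' @slot structures named list; each element is
#'   `list(mask = logical array, centroid = numeric(3), volume = numeric(1))`.
#' @slot spacing,origin,orientation grid geometry of the source volume.
#' @exportClass StructureSet
setClass("StructureSet", representation(
  structures = "list", spacing = "numeric", origin = "numeric",
  orientation = "matrix"))

setValidity("StructureSet", function(object) {
  msg <- character()
  if (is.null(names(object@structures)) || anyDuplicated(names(object@structures)))
    msg <- c(msg, "'structures' must be uniquely named")
  for (nm in names(object@structures)) {
    s <- object@structures[[nm]]
    if (!any(s$mask))
      msg <- c(msg, sprintf("structure '%s' has an empty mask", nm))
  }
  if (length(msg)) msg else TRUE
})

#' CameraModel: pinhole camera for AR mask rendering
#'
#' @slot focalLength focal length in pixels.
#' @slot principalPoint numeric(2) (cx, cy) in pixels, inside the image.
#' @slot imageSize integer(2) (width, height) in pixels.
#' @slot pose [RigidTransform-class] mapping world to camera
#'   coordinates; the camera looks along +z of its own frame.
#' @exportClass CameraModel
setClass("CameraModel", representation(
  focalLength = "numeric", principalPoint = "numeric",
  imageSize = "numeric", pose = "RigidTransform"))

setValidity("CameraModel", function(object) {
  msg <- character()
  if (object@focalLength <= 0) msg <- c(msg, "'focalLength' must be > 0")
  pp <- object@principalPoint
  sz <- object@imageSize
  if (!.isNumericLen(pp, 2) || !.isNumericLen(sz, 2))
    return("'principalPoint' and 'imageSize' must be numeric(2)")
  if (any(sz < 1)) msg <- c(msg, "'imageSize' must be >= 1")
  if (any(pp < 0) || any(pp > sz - 1))
    msg <- c(msg, "'principalPoint' must lie inside the image")
  if (length(msg)) msg else TRUE
})

#' Mask2D: binary pixel mask with provenance
#'
#' @slot pixels logical matrix, `dim = c(height, width)`; pixel (u, v)
#'   with 0-based coordinates is `pixels[v + 1, u + 1]`.
#' @slot tag provenance, one of "ar", "ground_truth" or "".
#' @exportClass Mask2D
setClass("Mask2D", representation(pixels = "matrix", tag = "character"))

setValidity("Mask2D", function(object) {
  msg <- character()
  if (!is.logical(object@pixels)) msg <- c(msg, "'pixels' must be logical")
  if (!object@tag %in% c("ar", "ground_truth", ""))
    msg <- c(msg, "'tag' must be \"ar\", \"ground_truth\" or \"\"")
  if (length(msg)) msg else TRUE
})

#' @describeIn Mask2D-class constructor.
#' @param pixels logical matrix (rows = image height).
#' @param tag provenance tag.
#' @export
mask2D <- function(pixels, tag = "") {
  new("Mask2D", pixels = pixels, tag = tag)
}
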