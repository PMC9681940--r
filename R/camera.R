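#' @include AllClasses.R transforms.R volume.R
NULL

#' Construct a pinhole camera
#'
#' @param focalLength focal length in pixels.
#' @param principalPoint numeric(2) (cx, cy), pixels, 0-based.
#' @param imageSize numeric(2) (width, height), pixels.
#' @param pose [RigidTransform-class] mapping world (mm) to camera
#'   coordinates; the camera looks along its +z axis.
#' @return A [CameraModel-class].
#' @export
cameraModel <- function(focalLength = 1000, principalPoint = c(640, 360),
                        imageSize = c(1280, 720), pose = identityTransform()) {
  new("CameraModel", focalLength = focalLength,
      principalPoint = as.numeric(principalPoint),
      imageSize = as.numeric(imageSize), pose = pose)
}

#' Default endoscope-like camera over the phantom
#'
#' Places the camera `distance` mm above the midpoint of the two SLN
#' spheres, looking straight down the board's z axis (camera axes:
#' x_cam = x_world, y_cam = -y_world, z_cam = -z_world, a proper
#' rotation), so both SLNs are in frame.
#'
#' @param spec a [PhantomSpec-class].
#' @param distance camera height above the SLN plane, mm.
#' @param focalLength,imageSize see [cameraModel()].
#' @return A [CameraModel-class].
#' @export
defaultCamera <- function(spec, distance = 245, focalLength = 1000,
                          imageSize = c(1280, 720)) {
  target <- colMeans(spec@slnCenters)
  C <- c(target[1], target[2], target[3] + distance)
  R <- diag(c(1, -1, -1))
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- -R %*% C
  cameraModel(focalLength, imageSize / 2, imageSize, rigidTransform(m))
}

#' Project world points through the camera
#'
#' Pinhole projection `u = f x/z + cx`, `v = f y/z + cy` in camera
#' coordinates, pixels, 0-based. All points must lie strictly in front
#' of the camera (positive depth).
#'
#' @param camera a [CameraModel-class].
#' @param points N x 3 matrix (or numeric(3)) of world points, mm.
#' @return N x 2 matrix (or numeric(2)) of pixel coordinates.
#' @examples
#' cam <- cameraModel()
#' projectPoints(cam, c(0, 0, 200))  # principal point (640, 360)
#' @export
projectPoints <- function(camera, points) {
  vec <- is.null(dim(points))
  p <- applyTransform(camera@pose, if (vec) matrix(points, 1) else points)
  if (any(p[, 3] <= 0))
    stop("point with non-positive depth cannot be projected")
  uv <- cbind(camera@focalLength * p[, 1] / p[, 3] + camera@principalPoint[1],
              camera@focalLength * p[, 2] / p[, 3] + camera@principalPoint[2])
  if (vec) drop(uv) else uv
}

#' Render a 3D segment as a 2D camera mask
#'
#' Maps every voxel centre of the (non-empty) segment by `transform`
#' (moving -> fixed/world), projects through the camera, rasterizes to
#' the nearest pixel, and solidifies the footprint by morphological
#' closing with a 3x3 structuring element. Voxels behind the camera or
#' outside the image are clipped; occlusion is deliberately ignored
#' (the overlay metrics are defined on plain 2D surfaces). A fully
#' out-of-frame segment yields an empty mask with a warning.
#'
#' @param camera a [CameraModel-class] (its pose maps fixed-session
#'   world coordinates to camera coordinates).
#' @param segment a [Volume3D-class] with 0/1 values (e.g. from
#'   [maskVolume()]), on the moving-session grid.
#' @param transform a [RigidTransform-class] mapping the segment's
#'   world frame to the camera's world frame.
#' @param tag provenance tag for the output mask.
#' @return A [Mask2D-class].
#' @export
renderSegmentMask <- function(camera, segment, transform = identityTransform(),
                              tag = "") {
  idx <- which(segment@values > 0.5)
  if (length(idx) == 0) stop("empty segment cannot be rendered")
  ijk <- arrayInd(idx, dim(segment@values)) - 1
  world <- applyTransform(transform, voxelToWorld(segment, ijk))
  p <- applyTransform(camera@pose, world)
  keep <- p[, 3] > 0
  w <- as.integer(camera@imageSize[1])
  h <- as.integer(camera@imageSize[2])
  px <- matrix(FALSE, h, w)
  if (any(keep)) {
    u <- round(camera@focalLength * p[keep, 1] / p[keep, 3] +
                 camera@principalPoint[1])
    v <- round(camera@focalLength * p[keep, 2] / p[keep, 3] +
                 camera@principalPoint[2])
    inFrame <- u >= 0 & u < w & v >= 0 & v < h
    u <- u[inFrame]; v <- v[inFrame]
    if (length(u)) px[cbind(v + 1, u + 1)] <- TRUE
  }
  if (!any(px)) {
    warning("segment projects fully outside the image: empty mask")
    return(mask2D(px, tag))
  }
  closed <- EBImage::closing(px + 0, EBImage::makeBrush(3, "box"))
  mask2D(closed > 0.5, tag)
}

#' Render the AR / ground-truth overlay mask pair
#'
#' `s1` is the augmented-reality mask, rendered with the *estimated*
#' registration transform; `s2` is the ground-truth visible mask,
#' rendered from the same segment with the *true* transform (the
#' digital stand-in for the lymph node seen in the endoscopic image).
#'
#' @inheritParams renderSegmentMask
#' @param tEstimated,tTrue estimated and true
#'   [RigidTransform-class]s (moving -> fixed world).
#' @return list with elements `s1` and `s2` ([Mask2D-class]).
#' @export
makeOverlayPair <- function(camera, segment, tEstimated, tTrue) {
  list(s1 = renderSegmentMask(camera, segment, tEstimated, tag = "ar"),
       s2 = renderSegmentMask(camera, segment, tTrue, tag = "ground_truth"))
}
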