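#' @include AllClasses.R
NULL

#' Construct rigid transforms
#'
#' `rigidTransform` wraps a 4x4 homogeneous matrix;
#' `rigidTransformFromParams` builds one from Euler angles (degrees,
#' applied as Rz Ry Rx) and a translation, optionally rotating about a
#' centre point; `identityTransform` returns the identity map.
#'
#' @param matrix 4x4 homogeneous matrix (rotation block det +1).
#' @param angles numeric(3) rotations about x, y, z in degrees.
#' @param translation numeric(3) translation in mm.
#' @param center numeric(3) rotation centre in mm.
#' @return A [RigidTransform-class].
#' @examples
#' t <- rigidTransformFromParams(c(10, 0, 0), c(1, 2, 3))
#' transformMatrix(composeTransforms(t, invertTransform(t)))
#' @export
rigidTransform <- function(matrix) new("RigidTransform", matrix = matrix)

#' @rdname rigidTransform
#' @export
identityTransform <- function() rigidTransform(diag(4))

.rotX <- function(a) rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
.rotY <- function(a) rbind(c(cos(a), 0, sin(a)), c(0, 1, 0), c(-sin(a), 0, cos(a)))
.rotZ <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))

#' @rdname rigidTransform
#' @export
rigidTransformFromParams <- function(angles = c(0, 0, 0),
                                     translation = c(0, 0, 0),
                                     center = c(0, 0, 0)) {
  a <- angles * pi / 180
  R <- .rotZ(a[3]) %*% .rotY(a[2]) %*% .rotX(a[1])
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- center - R %*% center + translation
  rigidTransform(m)
}

#' Rotation about an arbitrary axis
#'
#' Rodrigues rotation by `angleDeg` degrees about unit `axis`, rotating
#' about `center`, plus `translation`.
#'
#' @param axis numeric(3), need not be normalized.
#' @param angleDeg rotation angle in degrees.
#' @param translation numeric(3) mm.
#' @param center rotation centre, mm.
#' @return A [RigidTransform-class].
#' @export
rigidTransformAxisAngle <- function(axis, angleDeg, translation = c(0, 0, 0),
                                    center = c(0, 0, 0)) {
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("rotation axis must be non-zero")
  k <- axis / n
  a <- angleDeg * pi / 180
  K <- rbind(c(0, -k[3], k[2]), c(k[3], 0, -k[1]), c(-k[2], k[1], 0))
  R <- diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- center - R %*% center + translation
  rigidTransform(m)
}

#' Compose, invert and apply rigid transforms
#'
#' `composeTransforms(a, b)` returns the transform applying `b` first
#' and then `a` (matrix product `a %*% b`). `invertTransform` exploits
#' rigidity (`R^-1 = R^T`). `applyTransform` maps an N x 3 matrix (or a
#' length-3 vector) of world points.
#'
#' @param a,b,transform [RigidTransform-class] objects.
#' @param points N x 3 matrix or numeric(3), mm.
#' @return A transform, or the mapped points with the input shape.
#' @export
composeTransforms <- function(a, b) rigidTransform(a@matrix %*% b@matrix)

#' @rdname composeTransforms
#' @export
invertTransform <- function(transform) {
  m <- transform@matrix
  R <- t(m[1:3, 1:3])
  inv <- diag(4)
  inv[1:3, 1:3] <- R
  inv[1:3, 4] <- -R %*% m[1:3, 4]
  rigidTransform(inv)
}

#' @rdname composeTransforms
#' @export
applyTransform <- function(transform, points) {
  vec <- is.null(dim(points))
  p <- if (vec) matrix(points, 1) else points
  out <- p %*% t(transform@matrix[1:3, 1:3])
  out <- sweep(out, 2, transform@matrix[1:3, 4], "+")
  if (vec) drop(out) else out
}

#' Rotation angle and translation norm of a rigid transform
#'
#' `rotationAngle` is the geodesic rotation angle in degrees;
#' `rotationBetween` the angle between the rotation blocks of two
#' transforms (degrees); `translationNorm` the Euclidean norm of the
#' translation component (mm).
#'
#' @param transform,a,b [RigidTransform-class] objects.
#' @return scalar.
#' @export
rotationAngle <- function(transform) {
  R <- transform@matrix[1:3, 1:3]
  acos(min(1, max(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

#' @rdname rotationAngle
#' @export
rotationBetween <- function(a, b) {
  rotationAngle(rigidTransform(composeTransforms(a, invertTransform(b))@matrix))
}

#' @rdname rotationAngle
#' @export
translationNorm <- function(transform) sqrt(sum(transform@matrix[1:3, 4]^2))

#' Draw a bounded random rigid misalignment
#'
#' Emulates the unknown repositioning of the phantom between the
#' preoperative SPECT/CT session and the intraoperative CT session:
#' a rotation of uniformly drawn angle (at most `maxRotationDeg`) about
#' a uniformly random axis through `center`, plus a translation of
#' uniformly drawn norm (at most `maxTranslationMm`) in a uniformly
#' random direction. Deterministic for a fixed `seed`.
#'
#' @param maxRotationDeg,maxTranslationMm non-negative bounds.
#' @param seed integer RNG seed.
#' @param center rotation centre in mm (typically the phantom centre).
#' @return A [RigidTransform-class].
#' @examples
#' t <- sampleRigidMisalignment(10, 20, seed = 1, center = c(90, 70, 55))
#' rotationAngle(t) <= 10
#' @export
sampleRigidMisalignment <- function(maxRotationDeg, maxTranslationMm, seed,
                                    center = c(0, 0, 0)) {
  if (maxRotationDeg < 0 || maxTranslationMm < 0)
    stop("misalignment bounds must be >= 0")
  if (maxRotationDeg == 0 && maxTranslationMm == 0)
    return(identityTransform())
  set.seed(seed)
  axis <- rnorm(3)
  while (sum(axis^2) < 1e-12) axis <- rnorm(3)
  angle <- runif(1, 0, maxRotationDeg)
  dir <- rnorm(3)
  while (sum(dir^2) < 1e-12) dir <- rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  trans <- dir * runif(1, 0, maxTranslationMm)
  rigidTransformAxisAngle(axis, angle, trans, center)
}

#' Read and write 4x4 transform matrices as plain text
#'
#' Row-major, whitespace-separated, four values per line; the matrix
#' maps moving-session world coordinates (mm) to fixed-session world
#' coordinates.
#'
#' @param transform a [RigidTransform-class].
#' @param path file path.
#' @return `readTransform` returns a [RigidTransform-class];
#'   `writeTransform` returns `path` invisibly.
#' @export
writeTransform <- function(transform, path) {
  m <- transform@matrix
  writeLines(apply(m, 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " ")), path)
  invisible(path)
}

#' @rdname writeTransform
#' @export
readTransform <- function(path) {
  vals <- scan(path, quiet = TRUE)
  if (length(vals) != 16) stop("expected 16 values in ", path)
  rigidTransform(matrix(vals, 4, 4, byrow = TRUE))
}
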