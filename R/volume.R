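#' @include AllClasses.R transforms.R
NULL

# 4x4 affine mapping 0-based voxel indices to world mm.
.indexToWorld <- function(vol) {
  m <- diag(4)
  m[1:3, 1:3] <- vol@orientation %*% diag(vol@spacing)
  m[1:3, 4] <- vol@origin
  m
}

.worldToIndex <- function(vol) solve(.indexToWorld(vol))

#' Convert between voxel indices and world coordinates
#'
#' Voxel indices are 0-based and address voxel centres.
#'
#' @param vol a [Volume3D-class].
#' @param idx N x 3 matrix (or numeric(3)) of 0-based voxel indices.
#' @param pts N x 3 matrix (or numeric(3)) of world coordinates, mm.
#' @return the converted coordinates, same shape as the input.
#' @export
voxelToWorld <- function(vol, idx) {
  vec <- is.null(dim(idx))
  p <- if (vec) matrix(idx, 1) else idx
  out <- sweep(p %*% t(vol@orientation %*% diag(vol@spacing)), 2, vol@origin, "+")
  if (vec) drop(out) else out
}

#' @rdname voxelToWorld
#' @export
worldToVoxel <- function(vol, pts) {
  vec <- is.null(dim(pts))
  p <- if (vec) matrix(pts, 1) else pts
  out <- sweep(p, 2, vol@origin) %*% t(diag(1 / vol@spacing) %*% t(vol@orientation))
  if (vec) drop(out) else out
}

#' Resample a volume onto a reference grid under a rigid transform
#'
#' Samples `moving` on the voxel grid of `reference` after applying
#' `transform` (which maps moving-volume world coordinates to
#' reference/fixed world coordinates). Scalar volumes use trilinear
#' interpolation; label maps and binary masks should use
#' `interpolation = "nearest"`. Voxels that fall outside the moving
#' grid receive `fill` (use `NA` to mark them for exclusion, e.g. from
#' a similarity metric).
#'
#' @param moving a [Volume3D-class] to resample.
#' @param transform a [RigidTransform-class], moving -> fixed world.
#' @param reference a [Volume3D-class] supplying the output grid.
#' @param interpolation "linear" or "nearest".
#' @param fill value for out-of-field voxels.
#' @return A [Volume3D-class] on the reference grid (a [LabelMap-class]
#'   if `moving` is one and interpolation is nearest).
#' @examples
#' v <- volume3D(array(rnorm(64), c(4, 4, 4)))
#' r <- resampleVolume(v, identityTransform(), v)
#' all.equal(voxelValues(r), voxelValues(v))
#' @export
resampleVolume <- function(moving, transform, reference,
                           interpolation = c("linear", "nearest"),
                           fill = 0) {
  interpolation <- match.arg(interpolation)
  A <- .worldToIndex(moving) %*% invertTransform(transform)@matrix %*%
    .indexToWorld(reference)
  odim <- dim(reference@values)
  vals <- cpp_resample(as.numeric(moving@values), dim(moving@values), odim,
                       as.numeric(A), interpolation == "nearest", fill)
  dim(vals) <- odim
  out <- volume3D(vals, reference@spacing, reference@origin,
                  reference@orientation)
  if (is(moving, "LabelMap") && interpolation == "nearest")
    out <- new("LabelMap", out, labels = moving@labels)
  out
}

#' Separable Gaussian smoothing of a 3D array
#'
#' Zero-padded separable convolution with a Gaussian kernel truncated
#' at 4 standard deviations, used to model the SPECT point-spread
#' function. `sigma` is in voxels, per axis.
#'
#' @param arr numeric 3D array.
#' @param sigma numeric(3) (or scalar) standard deviation in voxels.
#' @return smoothed array of the same dimensions.
#' @export
gaussianSmooth3D <- function(arr, sigma) {
  if (length(sigma) == 1L) sigma <- rep(sigma, 3)
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(4 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    k <- k / sum(k)
    perm <- c(ax, setdiff(1:3, ax))
    x <- aperm(arr, perm)
    dp <- dim(x)
    m <- matrix(x, nrow = dp[1])
    padded <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
    f <- stats::filter(padded, k, method = "convolution", sides = 2)
    m <- f[(r + 1):(r + dp[1]), , drop = FALSE]
    x <- array(m, dp)
    arr <- aperm(x, order(perm))
  }
  arr
}

# Block-mean downsampling by an integer factor (dims cropped to a
# multiple of the factor); used for the registration pyramid.
.downsampleVolume <- function(vol, factor) {
  if (factor == 1L) return(vol)
  d <- dim(vol@values)
  nd <- d %/% factor
  v <- vol@values[seq_len(nd[1] * factor), seq_len(nd[2] * factor),
                  seq_len(nd[3] * factor), drop = FALSE]
  dim(v) <- c(factor, nd[1], factor, nd[2], factor, nd[3])
  v <- apply(v, c(2, 4, 6), mean)
  newSpacing <- vol@spacing * factor
  # first coarse voxel centre = mean of the first block's fine centres
  shift <- vol@orientation %*% ((factor - 1) / 2 * vol@spacing)
  volume3D(v, newSpacing, vol@origin + as.numeric(shift), vol@orientation)
}

# Refine a grid by an integer factor with nearest-neighbour sampling;
# used to rasterize segment masks finely before camera projection.
.refineVolume <- function(vol, factor) {
  if (factor == 1L) return(vol)
  d <- dim(vol@values)
  newSpacing <- vol@spacing / factor
  shift <- vol@orientation %*% ((1 / factor - 1) / 2 * vol@spacing)
  ref <- volume3D(array(0, d * factor), newSpacing,
                  vol@origin + as.numeric(shift), vol@orientation)
  resampleVolume(vol, identityTransform(), ref, "nearest", fill = 0)
}

# Crop a (mask) volume to the bounding box of its positive voxels,
# padded by `pad` voxels; grid geometry is preserved.
.cropToMask <- function(vol, pad = 1L) {
  idx <- which(vol@values > 0.5)
  if (length(idx) == 0) return(vol)
  ijk <- arrayInd(idx, dim(vol@values))
  lo <- pmax(1L, apply(ijk, 2, min) - pad)
  hi <- pmin(dim(vol@values), apply(ijk, 2, max) + pad)
  vals <- vol@values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  shift <- vol@orientation %*% ((lo - 1) * vol@spacing)
  volume3D(vals, vol@spacing, vol@origin + as.numeric(shift),
           vol@orientation)
}

# Geometric (or weighted) centroid in world mm and volume in mm^3 of a
# logical mask living on the grid of `vol`.
.maskCentroid <- function(mask, vol, weights = NULL) {
  idx <- which(mask)
  ijk <- arrayInd(idx, dim(mask)) - 1
  w <- if (is.null(weights)) rep(1, length(idx)) else weights[idx]
  ctrIdx <- colSums(ijk * w) / sum(w)
  list(centroid = as.numeric(voxelToWorld(vol, ctrIdx)),
       volume = length(idx) * prod(vol@spacing))
}

#' Extract one structure mask as a binary Volume3D
#'
#' @param structures a [StructureSet-class].
#' @param name structure name.
#' @return A [Volume3D-class] with 0/1 values on the set's grid.
#' @export
maskVolume <- function(structures, name) {
  s <- getStructure(structures, name)
  volume3D(s$mask + 0, structures@spacing, structures@origin,
           structures@orientation)
}
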