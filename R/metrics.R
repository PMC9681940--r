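#' @include AllClasses.R camera.R
NULL

.pixCoords <- function(mask) {
  px <- if (is(mask, "Mask2D")) mask@pixels else mask
  idx <- which(px, arr.ind = TRUE)
  # 0-based (u, v) = (column, row)
  cbind(u = idx[, 2] - 1, v = idx[, 1] - 1)
}

#' Barycenter of a 2D mask
#'
#' Arithmetic mean of the set pixels' 0-based (u, v) coordinates, at
#' sub-pixel precision.
#'
#' @param mask a [Mask2D-class] (or logical matrix), non-empty.
#' @return numeric(2) barycenter (u, v) in pixels.
#' @examples
#' m <- matrix(FALSE, 10, 10); m[4, 8] <- TRUE
#' barycenter(m)  # pixel (u = 7, v = 3)
#' @export
barycenter <- function(mask) {
  uv <- .pixCoords(mask)
  if (nrow(uv) == 0) stop("empty mask has no barycenter")
  colMeans(uv)
}

#' Area of a 2D mask in pixels
#' @param mask a [Mask2D-class] or logical matrix.
#' @return number of set pixels.
#' @export
maskArea <- function(mask) {
  px <- if (is(mask, "Mask2D")) mask@pixels else mask
  sum(px)
}

#' Pseudo-radius of a surface
#'
#' The theoretical (equivalent-disk) radius of a surface of the given
#' area, `sqrt(area / pi)`, in pixels.
#'
#' @param area surface area in pixels^2, > 0.
#' @return pseudo-radius in pixels.
#' @examples
#' pseudoRadius(100)  # 5.6419
#' @export
pseudoRadius <- function(area) {
  if (length(area) != 1 || !is.finite(area) || area <= 0)
    stop("area must be a single positive number")
  sqrt(area / pi)
}

#' Normalized barycenter distance between AR and ground-truth masks
#'
#' The Euclidean distance between the two barycenters divided by the
#' pseudo-radius: `Distance(b1, b2) / r`. The smaller the ratio (close
#' to 0), the more centred the registration is on the lymph node; a
#' ratio below 1 means the AR barycenter lies within one pseudo-radius
#' of the visible surface's barycenter. By default `r` is taken from
#' `s1`, the AR surface; `radiusFrom = "s2"` gives the variant
#' normalized by the visible surface.
#'
#' @param s1 AR [Mask2D-class]; @param s2 ground-truth [Mask2D-class].
#' @param radiusFrom which surface supplies the pseudo-radius.
#' @return dimensionless ratio >= 0.
#' @examples
#' m <- matrix(FALSE, 32, 32); m[3:12, 3:12] <- TRUE
#' shifted <- matrix(FALSE, 32, 32); shifted[7:16, 6:15] <- TRUE
#' normalizedBarycenterDistance(m, shifted)  # d = 5, r = 5.6419: 0.8862
#' @export
normalizedBarycenterDistance <- function(s1, s2, radiusFrom = c("s1", "s2")) {
  radiusFrom <- match.arg(radiusFrom)
  b1 <- barycenter(s1)
  b2 <- barycenter(s2)
  d <- sqrt(sum((b1 - b2)^2))
  r <- pseudoRadius(maskArea(if (radiusFrom == "s1") s1 else s2))
  d / r
}

#' Coverage rate of the visible surface by the AR surface
#'
#' `|s1 intersect s2| / |s2|`: the fraction of the ground-truth visible
#' surface covered by the augmented-reality surface. Masks must live on
#' identical pixel grids; mismatched sizes are an error, never silently
#' resized.
#'
#' @param s1 AR mask; @param s2 non-empty ground-truth mask
#'   ([Mask2D-class] or logical matrix).
#' @return fraction in `[0, 1]`.
#' @export
coverageRate <- function(s1, s2) {
  p1 <- if (is(s1, "Mask2D")) s1@pixels else s1
  p2 <- if (is(s2, "Mask2D")) s2@pixels else s2
  if (!identical(dim(p1), dim(p2)))
    stop("masks must share the same pixel grid")
  n2 <- sum(p2)
  if (n2 == 0) stop("empty ground-truth mask s2")
  sum(p1 & p2) / n2
}

#' Overlay accuracy report for one SLN mask pair
#'
#' Computes all per-node overlay statistics: areas of s1 and s2,
#' barycenters b1 and b2, their distance d, the pseudo-radius r of the
#' AR surface s1 (primary) and of s2 (variant), the normalized
#' barycenter distance d/r for both, and the coverage rate.
#'
#' @param s1,s2 AR and ground-truth [Mask2D-class] objects.
#' @param side label for the report row (e.g. "left").
#' @return one-row data.frame.
#' @export
overlayReport <- function(s1, s2, side = "") {
  b1 <- barycenter(s1); b2 <- barycenter(s2)
  a1 <- maskArea(s1); a2 <- maskArea(s2)
  d <- sqrt(sum((b1 - b2)^2))
  r1 <- pseudoRadius(a1); r2 <- pseudoRadius(a2)
  data.frame(side = side, area_s1 = a1, area_s2 = a2,
             b1_u = b1[[1]], b1_v = b1[[2]], b2_u = b2[[1]], b2_v = b2[[2]],
             d = d, r = r1, ratio = d / r1, ratio_r2 = d / r2,
             coverage = coverageRate(s1, s2), row.names = NULL)
}
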