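#' @include AllClasses.R volume.R
NULL

# Label the connected components (26-connectivity) of a logical array
# and return them as a list of masks sorted by decreasing size, ties
# broken by first voxel in column-major order (deterministic and
# independent of voxel iteration order).
.components <- function(mask, minVoxels = 1L) {
  lab <- cpp_label3d(as.logical(mask), dim(mask))
  ncomp <- attr(lab, "n")
  if (ncomp == 0) return(list())
  sizes <- tabulate(lab, nbins = ncomp)
  keep <- which(sizes >= minVoxels)
  keep <- keep[order(-sizes[keep], keep)]
  dim(lab) <- dim(mask)
  lapply(keep, function(k) lab == k)
}

.newStructureSet <- function(structures, vol) {
  new("StructureSet", structures = structures, spacing = vol@spacing,
      origin = vol@origin, orientation = vol@orientation)
}

#' Threshold-based segmentation of a CT-like volume
#'
#' Per structure, voxels within the intensity interval are grouped into
#' 26-connected components and components below `minComponentVoxels`
#' are discarded. The interval named `"sln"` is special: its two
#' largest components become the SLN candidates and are assigned
#' anatomical sides with [assignLeftRight()]. The interval named
#' `"fiducial"` yields one structure per component
#' (`fiducial_01`, ...), ordered by component size. Centroids of CT
#' masks are geometric (intensity-unweighted).
#'
#' @param volume a [Volume3D-class] CT-like image.
#' @param thresholds named list of `c(lo, hi)` intensity intervals;
#'   intervals must not overlap. Default matches [ctModel()].
#' @param minComponentVoxels smallest component kept, in voxels.
#' @return A [StructureSet-class].
#' @examples
#' lm <- buildPhantomLabelMap(defaultPhantomSpec(), voxelSize = 2)
#' ct <- renderCT(lm, ctModel(voxelSize = 2, noiseSigma = 0))
#' structureNames(segmentCT(ct))
#' @export
segmentCT <- function(volume,
                      thresholds = list(bone = c(900, 1350),
                                        vessel = c(150, 450),
                                        sln = c(480, 720),
                                        fiducial = c(1380, 1650)),
                      minComponentVoxels = 10L) {
  iv <- do.call(rbind, thresholds)
  if (nrow(iv) > 1) {
    o <- order(iv[, 1])
    if (any(iv[o, 2][-nrow(iv)] > iv[o, 1][-1]))
      stop("threshold intervals overlap")
  }
  vals <- volume@values
  out <- list()
  for (nm in names(thresholds)) {
    lohi <- thresholds[[nm]]
    sel <- vals >= lohi[1] & vals <= lohi[2]
    if (!any(sel))
      stop("no voxel in the intensity interval for structure '", nm, "'")
    comps <- .components(sel, minComponentVoxels)
    if (length(comps) == 0)
      stop("all components for structure '", nm,
           "' are smaller than min_component_voxels")
    if (nm == "sln") {
      if (length(comps) < 2)
        stop("expected two SLN-intensity components, found ", length(comps))
      for (i in 1:2) {
        cm <- .maskCentroid(comps[[i]], volume)
        out[[paste0("sln_cand_", i)]] <-
          list(mask = comps[[i]], centroid = cm$centroid, volume = cm$volume)
      }
    } else if (nm == "fiducial") {
      for (i in seq_along(comps)) {
        cm <- .maskCentroid(comps[[i]], volume)
        out[[sprintf("fiducial_%02d", i)]] <-
          list(mask = comps[[i]], centroid = cm$centroid, volume = cm$volume)
      }
    } else {
      m <- Reduce(`|`, comps)
      cm <- .maskCentroid(m, volume)
      out[[nm]] <- list(mask = m, centroid = cm$centroid, volume = cm$volume)
    }
  }
  set <- .newStructureSet(out, volume)
  if (any(grepl("^sln_cand_", names(out)))) set <- assignLeftRight(set)
  set
}

#' Isocontour segmentation of SPECT hotspots
#'
#' Thresholds the activity map at `fractionOfMax` of its global
#' maximum, splits the result into 26-connected components, and keeps
#' the two largest as the SLN hotspots. Hotspot centroids are
#' intensity-weighted, which under PSF blur is the better estimator of
#' the underlying sphere centre.
#'
#' The default isocontour is deliberately low: partial-volume dilution
#' under a 10 mm FWHM point-spread function leaves the peak of a
#' sub-FWHM 8 mm node at barely a quarter of the 15 mm node's peak, so
#' a global isocontour much above that fraction can only ever see the
#' larger node. With no background activity, a low threshold is safe.
#'
#' @param volume a [Volume3D-class] SPECT-like activity map.
#' @param fractionOfMax isocontour level in (0, 1).
#' @return A [StructureSet-class] with `sln_left` and `sln_right`.
#' @export
segmentSpectHotspots <- function(volume, fractionOfMax = 0.15) {
  if (fractionOfMax <= 0 || fractionOfMax >= 1)
    stop("fractionOfMax must be in (0, 1)")
  mx <- max(volume@values)
  if (mx <= 0) stop("activity map has no positive maximum")
  sel <- volume@values >= fractionOfMax * mx
  comps <- .components(sel)
  if (length(comps) < 2)
    stop("expected two hotspots above the isocontour, found ",
         length(comps))
  out <- list()
  for (i in 1:2) {
    cm <- .maskCentroid(comps[[i]], volume, weights = volume@values)
    out[[paste0("sln_cand_", i)]] <-
      list(mask = comps[[i]], centroid = cm$centroid, volume = cm$volume)
  }
  assignLeftRight(.newStructureSet(out, volume))
}

#' Name the two SLN candidates anatomically
#'
#' The candidate whose centroid has the smaller first world coordinate
#' becomes `sln_left`, the other `sln_right`, independent of input
#' order. An exact tie on the coordinate falls back to the documented
#' tie-break -- the larger-volume candidate becomes `sln_right` -- and
#' is logged via a message.
#'
#' @param structures a [StructureSet-class] with exactly two SLN
#'   candidates (names starting `sln_cand_` or already `sln_left`/`sln_right`).
#' @return The [StructureSet-class] with candidates renamed.
#' @export
assignLeftRight <- function(structures) {
  nms <- names(structures@structures)
  cand <- which(grepl("^sln_cand_", nms) | nms %in% c("sln_left", "sln_right"))
  if (length(cand) != 2)
    stop("expected exactly two SLN candidates, found ", length(cand))
  s <- structures@structures[cand]
  x <- vapply(s, function(el) el$centroid[1], numeric(1))
  if (x[1] == x[2]) {
    v <- vapply(s, `[[`, numeric(1), "volume")
    message("assignLeftRight: tie on first world coordinate; ",
            "larger-volume candidate assigned to the right")
    ord <- order(v)  # smaller volume -> left
  } else {
    ord <- order(x)
  }
  nms[cand[ord]] <- c("sln_left", "sln_right")
  names(structures@structures) <- nms
  structures
}

# All permutations of 1..n (n small), in lexicographic order; cached.
.permCache <- new.env(parent = emptyenv())
.permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(.permCache[[key]])) return(.permCache[[key]])
  gen <- function(n) {
    if (n == 1) return(matrix(1L, 1, 1))
    sub <- gen(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(k) {
      rest <- seq_len(n)[-k]
      cbind(k, matrix(rest[sub], nrow(sub)))
    }))
  }
  .permCache[[key]] <- gen(n)
  .permCache[[key]]
}

#' Detect and order fiducials in a CT-like volume
#'
#' Detects the fiducial spheres by thresholding, computes their
#' geometric centroids, and matches detections to the `expected`
#' ordering by exhaustive assignment minimizing the total discrepancy
#' between the two inter-point distance matrices. The matching is
#' invariant to rigid motion of the whole board, so `expected` may be
#' given in a different session frame than the detections.
#'
#' @param volume a [Volume3D-class] CT-like image.
#' @param expected Kx3 matrix (K >= 4) of fiducial positions in any
#'   rigidly related frame (e.g. the [PhantomSpec-class] fiducials).
#' @param intensityRange detection interval, default matching [ctModel()].
#' @param minVoxels smallest accepted component.
#' @return Kx3 matrix of detected centroids (mm, volume world frame),
#'   row k corresponding to `expected[k, ]`.
#' @export
detectFiducials <- function(volume, expected,
                            intensityRange = c(1380, 1650),
                            minVoxels = 5L) {
  if (is.null(dim(expected)) || nrow(expected) < 4)
    stop("at least 4 expected fiducials are required")
  nExp <- nrow(expected)
  if (nExp > 9) stop("exhaustive matching supports at most 9 fiducials")
  sel <- volume@values >= intensityRange[1] & volume@values <= intensityRange[2]
  comps <- .components(sel, minVoxels)
  if (length(comps) < nExp)
    stop("detected ", length(comps), " fiducials but ", nExp,
         " were expected")
  comps <- comps[seq_len(nExp)]  # largest n if spurious detections
  det <- do.call(rbind, lapply(comps, function(m)
    .maskCentroid(m, volume)$centroid))
  dExp <- as.matrix(stats::dist(expected))
  dDet <- as.matrix(stats::dist(det))
  perms <- .permutations(nExp)
  # vectorized cost over all permutations: for each (i, j) pair the
  # permuted distance dDet[p[i], p[j]] is gathered by linear indexing
  cost <- numeric(nrow(perms))
  for (i in seq_len(nExp)) for (j in seq_len(nExp)) {
    if (i == j) next
    cost <- cost + abs(dDet[perms[, i] + (perms[, j] - 1L) * nExp] - dExp[i, j])
  }
  det[perms[which.min(cost), ], , drop = FALSE]
}
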