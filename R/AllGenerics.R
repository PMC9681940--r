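#' @include AllClasses.R
NULL

#' Grid geometry accessors
#'
#' `spacing`, `origin` and `orientation` return the voxel size (mm),
#' the world position of the first voxel centre (mm) and the 3x3
#' direction matrix of a gridded object; `voxelValues` returns the raw
#' array.
#'
#' @param object a [Volume3D-class] or [StructureSet-class].
#' @return numeric vector, matrix or array as appropriate.
#' @aliases spacing origin orientation voxelValues
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))
#' @rdname spacing
#' @export
setGeneric("origin", function(object) standardGeneric("origin"))
#' @rdname spacing
#' @export
setGeneric("orientation", function(object) standardGeneric("orientation"))
#' @rdname spacing
#' @export
setGeneric("voxelValues", function(object) standardGeneric("voxelValues"))

setMethod("spacing", "Volume3D", function(object) object@spacing)
setMethod("origin", "Volume3D", function(object) object@origin)
setMethod("orientation", "Volume3D", function(object) object@orientation)
setMethod("voxelValues", "Volume3D", function(object) object@values)
setMethod("spacing", "StructureSet", function(object) object@spacing)
setMethod("origin", "StructureSet", function(object) object@origin)
setMethod("orientation", "StructureSet", function(object) object@orientation)

#' @export
setMethod("dim", "Volume3D", function(x) dim(x@values))

#' Label dictionary of a LabelMap
#' @param object a [LabelMap-class].
#' @return named integer vector mapping structure names to codes.
#' @export
setGeneric("labelCodes", function(object) standardGeneric("labelCodes"))
setMethod("labelCodes", "LabelMap", function(object) object@labels)

#' Structure accessors for StructureSet
#'
#' `structureNames` lists the segmented structures; `getStructure`
#' returns one structure (mask, centroid, volume); `centroids` returns
#' the world-space centroid matrix (mm).
#'
#' @param object a [StructureSet-class].
#' @param name structure name.
#' @aliases structureNames getStructure centroids
#' @export
setGeneric("structureNames", function(object) standardGeneric("structureNames"))
#' @rdname structureNames
#' @export
setGeneric("getStructure", function(object, name) standardGeneric("getStructure"))
#' @rdname structureNames
#' @export
setGeneric("centroids", function(object) standardGeneric("centroids"))

setMethod("structureNames", "StructureSet", function(object) names(object@structures))
setMethod("getStructure", "StructureSet", function(object, name) {
  if (!name %in% names(object@structures))
    stop("unknown structure: ", name)
  object@structures[[name]]
})
setMethod("centroids", "StructureSet", function(object) {
  do.call(rbind, lapply(object@structures, `[[`, "centroid"))
})

#' 4x4 matrix of a rigid transform
#' @param object a [RigidTransform-class].
#' @return 4x4 homogeneous matrix.
#' @export
setGeneric("transformMatrix", function(object) standardGeneric("transformMatrix"))
setMethod("transformMatrix", "RigidTransform", function(object) object@matrix)

#' Binary pixel grid of a Mask2D
#' @param object a [Mask2D-class].
#' @return logical matrix (rows = height).
#' @export
setGeneric("maskPixels", function(object) standardGeneric("maskPixels"))
setMethod("maskPixels", "Mask2D", function(object) object@pixels)

setMethod("show", "Volume3D", function(object) {
  d <- dim(object@values)
  cat(sprintf("%s: %d x %d x %d voxels, spacing %s mm\n", class(object),
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x ")))
  cat(sprintf("  origin (%s) mm, value range [%.3g, %.3g]\n",
              paste(format(object@origin, digits = 4), collapse = ", "),
              min(object@values), max(object@values)))
  if (is(object, "LabelMap"))
    cat("  labels:", paste(names(object@labels), collapse = ", "), "\n")
})

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform (moving -> fixed world, mm):\n")
  print(round(object@matrix, 6))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0(
    "PhantomSpec: field of view %s mm\n",
    "  SLN spheres: %.1f mm (left) / %.1f mm (right)\n",
    "  %d fiducials (radius %.1f mm), %d vessel segments, bone type '%s'\n"),
    paste(object@fieldOfView, collapse = " x "),
    object@slnLeftDiameter, object@slnRightDiameter,
    nrow(object@fiducials), object@fiducialRadius,
    length(object@vesselPath), object@bone$type))
})

setMethod("show", "ModalityModel", function(object) {
  cat(sprintf("ModalityModel[%s]: voxel %s mm", object@kind,
              paste(format(object@voxelSize, digits = 3), collapse = " x ")))
  if (object@kind == "SPECT")
    cat(sprintf(", PSF FWHM %.1f mm", object@psfFwhm))
  cat("\n  intensities:",
      paste(sprintf("%s=%g", names(object@tissueIntensities),
                    object@tissueIntensities), collapse = ", "), "\n")
})

setMethod("show", "StructureSet", function(object) {
  cat(sprintf("StructureSet with %d structures on a %s mm grid:\n",
              length(object@structures),
              paste(format(object@spacing, digits = 3), collapse = " x ")))
  for (nm in names(object@structures)) {
    s <- object@structures[[nm]]
    cat(sprintf("  %-12s centroid (%s) mm, volume %.0f mm^3\n", nm,
                paste(format(s$centroid, digits = 4), collapse = ", "),
                s$volume))
  }
})

setMethod("show", "CameraModel", function(object) {
  cat(sprintf("CameraModel: f = %g px, image %d x %d, principal point (%g, %g)\n",
              object@focalLength, object@imageSize[1], object@imageSize[2],
              object@principalPoint[1], object@principalPoint[2]))
})

setMethod("show", "Mask2D", function(object) {
  cat(sprintf("Mask2D[%s]: %d x %d px, %d set\n",
              if (nzchar(object@tag)) object@tag else "untagged",
              ncol(object@pixels), nrow(object@pixels), sum(object@pixels)))
})
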