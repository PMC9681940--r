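#' @include AllClasses.R volume.R
NULL

#' Read and write volumes as NIfTI
#'
#' Spacing, origin and orientation are carried in the NIfTI sform
#' (code 2): the affine maps 0-based voxel indices to world mm exactly
#' as the package convention `origin + orientation %*% (spacing * i)`.
#'
#' @param volume a [Volume3D-class].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `readVolume` returns a [Volume3D-class]; `writeVolume`
#'   returns `path` invisibly.
#' @export
writeVolume <- function(volume, path) {
  img <- RNifti::asNifti(volume@values)
  aff <- structure(.indexToWorld(volume), code = 2L)
  img <- RNifti::`sform<-`(img, aff)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  M <- aff[1:3, 1:3]
  sp <- sqrt(colSums(M^2))
  volume3D(array(as.numeric(img), dim(img)), spacing = sp,
           origin = as.numeric(aff[1:3, 4]),
           orientation = M %*% diag(1 / sp))
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask a [Mask2D-class].
#' @param path file path.
#' @export
writeMask <- function(mask, path) {
  png::writePNG(mask@pixels * 1, path)
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path, tag = "") {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  mask2D(m > 0.5, tag)
}

#' Export a StructureSet as a NIfTI labelmap plus JSON summary
#'
#' Writes one integer labelmap (structures numbered in order) and a
#' JSON file listing name, label, centroid (mm) and volume (mm^3) per
#' structure.
#'
#' @param structures a [StructureSet-class].
#' @param prefix output path prefix; writes `<prefix>.nii.gz` and
#'   `<prefix>.json`.
#' @export
writeStructureSet <- function(structures, prefix) {
  nms <- structureNames(structures)
  first <- getStructure(structures, nms[1])$mask
  lab <- array(0, dim(first))
  for (i in seq_along(nms))
    lab[getStructure(structures, nms[i])$mask] <- i
  vol <- volume3D(lab, structures@spacing, structures@origin,
                  structures@orientation)
  writeVolume(vol, paste0(prefix, ".nii.gz"))
  summary <- lapply(seq_along(nms), function(i) {
    s <- getStructure(structures, nms[i])
    list(name = nms[i], label = i, centroid_mm = s$centroid,
         volume_mm3 = s$volume)
  })
  jsonlite::write_json(summary, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

.writeSeedOutputs <- function(rec, outputDir) {
  dir <- file.path(outputDir, sprintf("seed_%d", rec$seed))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeVolume(rec$volumes$ctIntra, file.path(dir, "ct_intraop.nii.gz"))
  writeVolume(rec$volumes$ctPre, file.path(dir, "ct_preop.nii.gz"))
  writeVolume(rec$volumes$spectPre, file.path(dir, "spect_preop.nii.gz"))
  writeTransform(rec$true, file.path(dir, "misalignment_true.txt"))
  writeTransform(rec$trueInverse, file.path(dir, "registration_true.txt"))
  writeTransform(rec$estimated, file.path(dir, "registration_estimated.txt"))
  for (side in names(rec$masks)) {
    writeMask(rec$masks[[side]]$s1, file.path(dir, paste0(side, "_s1_ar.png")))
    writeMask(rec$masks[[side]]$s2,
              file.path(dir, paste0(side, "_s2_ground_truth.png")))
  }
  write.csv(rec$overlay, file.path(dir, "overlay.csv"), row.names = FALSE)
  invisible(dir)
}

#' Write the experiment report as JSON and CSV
#'
#' `report.json` holds the aggregate statistics, per-seed matrices and
#' metrics, and the echoed configuration; `overlay.csv` has one row
#' per seed and SLN. No timestamps are written, so a rerun with the
#' same configuration reproduces both files byte for byte.
#'
#' @param report an `ExperimentReport` from [runExperiment()].
#' @param outputDir output directory (created if needed).
#' @export
writeExperimentReport <- function(report, outputDir) {
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  ok <- Filter(function(r) is.null(r$error), report$records)
  seeds <- lapply(ok, function(r) list(
    seed = r$seed,
    true_matrix = r$true@matrix,
    estimated_matrix = r$estimated@matrix,
    fre_mm = r$fre, tre_mm = as.list(r$tre),
    mi_bits = r$mi, converged = r$converged,
    n_evaluations = r$nEvaluations,
    hotspot_agreement_mm = as.list(r$hotspotAgreement)))
  jsonlite::write_json(
    list(aggregate = report$aggregate, seeds = seeds,
         errors = report$errors, config = report$config),
    file.path(outputDir, "report.json"),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  write.csv(report$overlay, file.path(outputDir, "overlay.csv"),
            row.names = FALSE)
  invisible(outputDir)
}
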