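test_that("noiseless CT segmentation recovers the SLN masks (Dice > 0.95)", {
  ct <- noiselessCT1mm()
  lm <- defaultLabelMap1mm()
  seg <- segmentCT(ct)
  for (side in c("sln_left", "sln_right")) {
    truth <- voxelValues(lm) == labelCodes(lm)[[side]]
    mask <- getStructure(seg, side)$mask
    expect_gt(diceCoefficient(mask, truth), 0.95)
  }
  expect_true(all(c("bone", "vessel") %in% structureNames(seg)))
})

test_that("segmentation of an identity render reproduces generator centroids", {
  ct <- noiselessCT1mm()
  seg <- segmentCT(ct)
  spec <- defaultPhantomSpec()
  for (i in 1:2) {
    side <- c("sln_left", "sln_right")[i]
    d <- sqrt(sum((getStructure(seg, side)$centroid - spec@slnCenters[i, ])^2))
    expect_lt(d, 1)  # within one CT voxel
  }
})

test_that("structure-free intervals raise named errors", {
  flat <- volume3D(array(50, c(20, 20, 20)))
  expect_error(segmentCT(flat), "bone")
  ct <- noiselessCT1mm()
  expect_error(segmentCT(ct, thresholds = list(bone = c(900, 1350)),
                         minComponentVoxels = 1e7),
               "min_component_voxels")
  expect_error(segmentCT(ct, thresholds = list(bone = c(900, 1350),
                                               vessel = c(1000, 1400))),
               "overlap")
})

test_that("SPECT hotspot segmentation finds both spheres accurately", {
  sp <- noiselessSPECT()
  hot <- segmentSpectHotspots(sp)
  spec <- defaultPhantomSpec()
  for (i in 1:2) {
    side <- c("sln_left", "sln_right")[i]
    d <- sqrt(sum((getStructure(hot, side)$centroid - spec@slnCenters[i, ])^2))
    expect_lt(d, 4.4)  # within one SPECT voxel
  }
})

test_that("degenerate activity maps are rejected", {
  zero <- volume3D(array(0, c(10, 10, 10)), spacing = 4.4)
  expect_error(segmentSpectHotspots(zero), "positive maximum")
  # one smooth blob: near the peak only one tiny component survives
  blob <- array(0, c(20, 20, 20))
  blob[10, 10, 10] <- 100
  blob <- gaussianSmooth3D(blob, 2)
  expect_error(segmentSpectHotspots(volume3D(blob), 0.999), "found 1")
})

test_that("left/right naming follows the first world coordinate", {
  sp <- noiselessSPECT()
  hot <- segmentSpectHotspots(sp)
  expect_lt(getStructure(hot, "sln_left")$centroid[1],
            getStructure(hot, "sln_right")$centroid[1])
  # order invariance: swapping the candidate list changes nothing
  swapped <- new("StructureSet",
                 structures = rev(hot@structures),
                 spacing = spacing(hot), origin = origin(hot),
                 orientation = orientation(hot))
  names(swapped@structures) <- c("sln_cand_1", "sln_cand_2")
  renamed <- assignLeftRight(swapped)
  expect_equal(getStructure(renamed, "sln_left")$centroid,
               getStructure(hot, "sln_left")$centroid)
})

test_that("an exact left/right tie falls back to the volume tie-break", {
  mk <- function(vol) {
    mask <- array(FALSE, c(5, 5, 5)); mask[3, 3, 3] <- TRUE
    list(mask = mask, centroid = c(10, 10, 10), volume = vol)
  }
  set <- new("StructureSet",
             structures = list(sln_cand_1 = mk(1700), sln_cand_2 = mk(500)),
             spacing = rep(1, 3), origin = rep(0, 3), orientation = diag(3))
  expect_message(out <- assignLeftRight(set), "tie")
  expect_equal(getStructure(out, "sln_right")$volume, 1700)
  expect_equal(getStructure(out, "sln_left")$volume, 500)
})

test_that("fiducial detection is sub-voxel accurate on a noiseless render", {
  ct <- noiselessCT1mm()
  spec <- defaultPhantomSpec()
  det <- detectFiducials(ct, spec@fiducials)
  err <- sqrt(rowSums((det - spec@fiducials)^2))
  expect_lt(max(err), 0.5)  # within half a CT voxel
})

test_that("fiducial matching is invariant to frame and detection order", {
  ct <- noiselessCT1mm()
  spec <- defaultPhantomSpec()
  # expected positions given in a rigidly moved, row-permuted frame:
  # matching must still pair detection k with expected row k
  move <- rigidTransformFromParams(c(15, -10, 30), c(40, -25, 10),
                                   center = c(90, 70, 55))
  moved <- applyTransform(move, spec@fiducials)
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  det <- detectFiducials(ct, moved[perm, ])
  err <- sqrt(rowSums((det - spec@fiducials[perm, ])^2))
  expect_lt(max(err), 0.5)
})

test_that("fiducial preconditions and shortfalls are reported", {
  ct <- noiselessCT1mm()
  spec <- defaultPhantomSpec()
  expect_error(detectFiducials(ct, spec@fiducials[1:3, ]), "at least 4")
  expect_error(detectFiducials(ct, spec@fiducials, intensityRange = c(5e4, 6e4)),
               "detected 0")
})
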