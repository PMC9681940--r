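test_that("default phantom labelmap has two SLN labels, right one larger", {
  lm <- defaultLabelMap2mm()
  codes <- labelCodes(lm)
  counts <- table(voxelValues(lm))
  nLeft <- counts[[as.character(codes[["sln_left"]])]]
  nRight <- counts[[as.character(codes[["sln_right"]])]]
  expect_gt(nLeft, 0)
  expect_gt(nRight, nLeft)
  fidCodes <- codes[grepl("^fiducial_", names(codes))]
  expect_length(fidCodes, 8)
  for (code in fidCodes)
    expect_gt(sum(voxelValues(lm) == code), 0)
})

test_that("degenerate sphere diameters are rejected", {
  expect_error(defaultPhantomSpec(slnLeftDiameter = 0), "positive")
  expect_error(defaultPhantomSpec(slnRightDiameter = -3), "positive")
})

test_that("15 mm sphere voxel count matches the analytic volume at 1 mm", {
  lm <- defaultLabelMap1mm()
  n <- sum(voxelValues(lm) == labelCodes(lm)[["sln_right"]])
  analytic <- 4 / 3 * pi * 7.5^3
  expect_lt(abs(n - analytic) / analytic, 0.02)
})

test_that("halving the voxel size changes the 15 mm sphere volume < 1%", {
  spec <- smallSpec()
  v1 <- sum(voxelValues(buildPhantomLabelMap(spec, 1)) == 4) * 1^3
  v05 <- sum(voxelValues(buildPhantomLabelMap(spec, 0.5)) == 4) * 0.5^3
  expect_lt(abs(v1 - v05) / v05, 0.01)
})

test_that("label precedence puts fiducials and SLNs above bone/vessel", {
  # a spec whose right SLN overlaps the bone box: SLN wins
  spec <- smallSpec(slnCenters = rbind(left = c(25, 30, 30),
                                       right = c(45, 48, 30)))
  lm <- buildPhantomLabelMap(spec, 1)
  expect_gt(sum(voxelValues(lm) == 4), 0.95 * 4 / 3 * pi * 7.5^3)
})

test_that("noise-free identity CT render equals the label intensities", {
  lm <- defaultLabelMap2mm()
  ct <- renderCT(lm, ctModel(voxelSize = 2, noiseSigma = 0))
  expect_setequal(unique(as.vector(voxelValues(ct))),
                  c(40, 1200, 300, 600, 1500))
  # identity pose with matched voxel size: grids coincide voxelwise
  expect_equal(origin(ct), origin(lm))
  lut <- c(40, 1200, 300, 600, 600, rep(NA, 6), rep(1500, 8))
  expect_equal(as.vector(voxelValues(ct)),
               lut[as.vector(voxelValues(lm)) + 1])
})

test_that("CT renders are bit-reproducible per seed", {
  lm <- defaultLabelMap2mm()
  m <- ctModel(voxelSize = 2)
  a <- renderCT(lm, m, seed = 11)
  b <- renderCT(lm, m, seed = 11)
  c <- renderCT(lm, m, seed = 12)
  expect_identical(voxelValues(a), voxelValues(b))
  expect_false(identical(voxelValues(a), voxelValues(c)))
})

test_that("integer-voxel translation leaves the CT histogram unchanged", {
  lm <- defaultLabelMap2mm()
  m <- ctModel(voxelSize = 2, noiseSigma = 0)
  base <- renderCT(lm, m)
  shifted <- renderCT(lm, m,
                      pose = rigidTransformFromParams(translation = c(6, -4, 2)))
  expect_identical(table(voxelValues(base)), table(voxelValues(shifted)))
})

test_that("a pose ejecting an SLN from the field of view errors", {
  # strongly anisotropic FOV: a 90 deg rotation sends the right SLN's
  # 30 mm x-offset into y, where the half-extent is only 20 mm
  spec <- phantomSpec(
    slnLeftDiameter = 8, slnRightDiameter = 8,
    slnCenters = rbind(left = c(30, 20, 20), right = c(80, 20, 20)),
    vesselPath = list(list(points = rbind(c(50, 10, 10), c(60, 10, 10)),
                           radius = 2)),
    bone = list(type = "box", lower = c(40, 5, 5), upper = c(60, 35, 12)),
    fiducials = rbind(c(10, 10, 10), c(90, 12, 12), c(12, 30, 14),
                      c(88, 28, 30)),
    fiducialRadius = 4, fieldOfView = c(100, 40, 40))
  lm <- buildPhantomLabelMap(spec, 2)
  pose <- rigidTransformAxisAngle(c(0, 0, 1), 90, center = spec@fieldOfView / 2)
  expect_error(renderCT(lm, ctModel(voxelSize = 2, noiseSigma = 0), pose),
               "outside the field of view")
})

test_that("zero activity yields an all-zero SPECT volume", {
  lm <- defaultLabelMap2mm()
  sp <- renderSPECT(lm, spectModel(activity = 0), seed = 5)
  expect_true(all(voxelValues(sp) == 0))
})

test_that("the PSF convolution conserves total activity within 1%", {
  lm <- defaultLabelMap1mm()
  noBlur <- renderSPECT(lm, spectModel(psfFwhm = 0, poissonScale = 0))
  blur <- renderSPECT(lm, spectModel(psfFwhm = 10, poissonScale = 0))
  expect_lt(abs(sum(voxelValues(blur)) - sum(voxelValues(noBlur))) /
              sum(voxelValues(noBlur)), 0.01)
})

test_that("SPECT renders show one hotspot per SLN, larger on the right", {
  sp <- noiselessSPECT()
  v <- voxelValues(sp)
  spec <- defaultPhantomSpec()
  half <- round(worldToVoxel(sp, c(90, 75, 55)))[1]
  left <- v[seq_len(half), , ]
  right <- v[(half + 1):dim(v)[1], , ]
  expect_gt(max(left), 0)
  expect_gt(max(right), max(left))
  thr <- 0.15 * max(v)
  expect_gt(sum(right >= thr), sum(left >= thr))
})

test_that("SPECT renders are reproducible and Poisson noise is seeded", {
  lm <- defaultLabelMap2mm()
  m <- spectModel()
  a <- renderSPECT(lm, m, seed = 3)
  b <- renderSPECT(lm, m, seed = 3)
  expect_identical(voxelValues(a), voxelValues(b))
})

test_that("CT and SPECT renders co-locate the SLNs within one SPECT voxel", {
  ct <- noiselessCT1mm()
  sp <- noiselessSPECT()
  ctSeg <- segmentCT(ct)
  hot <- segmentSpectHotspots(sp)
  for (side in c("sln_left", "sln_right")) {
    d <- sqrt(sum((getStructure(ctSeg, side)$centroid -
                     getStructure(hot, side)$centroid)^2))
    expect_lt(d, 4.4)
  }
})
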