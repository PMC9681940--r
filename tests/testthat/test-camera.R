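test_that("pinhole projection follows the closed-form arithmetic", {
  cam <- cameraModel()  # identity pose: world = camera frame
  expect_equal(projectPoints(cam, c(0, 0, 200)), c(640, 360))
  expect_equal(projectPoints(cam, c(10, -5, 200)), c(690, 335))
  # doubling the focal length doubles the offset from the principal point
  cam2 <- cameraModel(focalLength = 2000)
  p1 <- projectPoints(cam, c(10, -5, 200)) - c(640, 360)
  p2 <- projectPoints(cam2, c(10, -5, 200)) - c(640, 360)
  expect_equal(p2, 2 * p1)
  expect_error(projectPoints(cam, c(0, 0, -5)), "depth")
  expect_error(projectPoints(cam, c(0, 0, 0)), "depth")
})

# sphere mask on a fine grid, centred at `centre` (camera frame, mm)
.sphereSegment <- function(radius, centre, spacing = 0.5) {
  n <- ceiling(2 * radius / spacing) + 4
  half <- (n - 1) / 2
  idx <- seq_len(n) - 1
  co <- (idx - half) * spacing
  d2 <- outer(outer(co^2, co^2, "+"), co^2, "+")
  volume3D((d2 <= radius^2) + 0, spacing = spacing,
           origin = centre - half * spacing)
}

test_that("a 15 mm sphere projects to a disk of radius f*R/z within 5%", {
  for (z in c(200, 245, 400)) {
    seg <- .sphereSegment(7.5, c(0, 0, z))
    m <- renderSegmentMask(cameraModel(), seg)
    r <- pseudoRadius(maskArea(m))
    expect_lt(abs(r - 1000 * 7.5 / z) / (1000 * 7.5 / z), 0.05)
  }
})

test_that("projected area scales as 1/z^2 within 5%", {
  a1 <- maskArea(renderSegmentMask(cameraModel(), .sphereSegment(7.5, c(0, 0, 200))))
  a2 <- maskArea(renderSegmentMask(cameraModel(), .sphereSegment(7.5, c(0, 0, 400))))
  expect_lt(abs(a1 / a2 - 4) / 4, 0.05)
})

test_that("degenerate segments are handled explicitly", {
  empty <- volume3D(array(0, c(5, 5, 5)))
  expect_error(renderSegmentMask(cameraModel(), empty), "empty segment")
  behind <- .sphereSegment(5, c(0, 0, -100))
  expect_warning(m <- renderSegmentMask(cameraModel(), behind), "outside")
  expect_equal(maskArea(m), 0)
  offFrame <- .sphereSegment(5, c(5000, 0, 200))
  expect_warning(m2 <- renderSegmentMask(cameraModel(), offFrame), "outside")
  expect_equal(maskArea(m2), 0)
})

test_that("the overlay pair is identical when estimated equals true", {
  seg <- .sphereSegment(4, c(0, 0, 245))
  t <- rigidTransformFromParams(c(1, -2, 3), c(2, 1, -2))
  pair <- makeOverlayPair(cameraModel(), seg,
                          tEstimated = t, tTrue = t)
  expect_identical(maskPixels(pair$s1), maskPixels(pair$s2))
  expect_equal(pair$s1@tag, "ar")
  expect_equal(pair$s2@tag, "ground_truth")
})

test_that("an in-plane translation shifts the mask by the projected offset", {
  z <- 245
  seg <- .sphereSegment(7.5, c(0, 0, z))
  dx <- 3  # mm in-plane
  pair <- makeOverlayPair(cameraModel(), seg,
                          tEstimated = rigidTransformFromParams(translation = c(dx, 0, 0)),
                          tTrue = identityTransform())
  shift <- barycenter(pair$s1) - barycenter(pair$s2)
  expect_equal(shift[[1]], 1000 * dx / z, tolerance = 0.05)
  expect_lt(abs(shift[[2]]), 0.2)
})

test_that("both SLNs yield disjoint in-frame mask pairs in the default view", {
  spec <- defaultPhantomSpec()
  cam <- defaultCamera(spec)
  masks <- list()
  for (i in 1:2) {
    r <- c(spec@slnLeftDiameter, spec@slnRightDiameter)[i] / 2
    seg <- .sphereSegment(r, spec@slnCenters[i, ])
    pair <- makeOverlayPair(cam, seg, identityTransform(), identityTransform())
    expect_gt(maskArea(pair$s1), 0)
    masks[[i]] <- pair$s1
  }
  expect_equal(sum(maskPixels(masks[[1]]) & maskPixels(masks[[2]])), 0)
})
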