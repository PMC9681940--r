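# fast experiment settings: coarse CT, two seeds, no MI refinement
.fastConfig <- function(seeds = 1:2, refine = FALSE) {
  list(ct = list(voxel_size = 2),
       misalignment = list(seeds = seeds),
       registration = list(refine = refine),
       overlay = list(upsample = 4))
}

test_that("an empty configuration file yields the echoed defaults", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines("", path)
  cfg <- validateConfig(path)
  expect_equal(cfg, defaultConfig())
})

test_that("configuration violations are named and collected", {
  expect_error(validateConfig(config = list(
    phantom = list(sln_left_diameter = -8))),
    "phantom.sln_left_diameter")
  err <- tryCatch(validateConfig(config = list(
    phantom = list(sln_left_diameter = -8),
    spect = list(psf_fwhm = -1))), error = identity)
  expect_match(conditionMessage(err), "sln_left_diameter")
  expect_match(conditionMessage(err), "psf_fwhm")
  expect_error(validateConfig(config = list(nonsense = 1)), "unknown")
  expect_error(validateConfig(config = list(ct = list(bogus_key = 2))),
               "ct.bogus_key")
})

test_that("configurations round-trip through JSON identically", {
  cfg <- validateConfig(config = list(
    misalignment = list(seeds = c(3, 7), max_rotation_deg = 5),
    camera = list(distance = 300)))
  path <- withr::local_tempfile(fileext = ".json")
  writeConfig(cfg, path)
  expect_equal(validateConfig(path), cfg)
})

test_that("oracle alignment yields exact unit coverage and zero ratio", {
  rep <- runExperiment(validateConfig(config = .fastConfig()),
                       oracle = TRUE, verbose = FALSE)
  expect_true(all(rep$overlay$coverage == 1))
  expect_true(all(rep$overlay$ratio == 0))
  expect_true(all(rep$overlay$area_s1 == rep$overlay$area_s2))
})

test_that("experiment runs are deterministic and seed-independent", {
  r1 <- runExperiment(validateConfig(config = .fastConfig(seeds = 1:2)),
                      verbose = FALSE)
  r2 <- runExperiment(validateConfig(config = .fastConfig(seeds = 1:2)),
                      verbose = FALSE)
  expect_equal(r1$overlay, r2$overlay)
  expect_identical(transformMatrix(r1$records[["1"]]$estimated),
                   transformMatrix(r2$records[["1"]]$estimated))
  # cross-seed independence: seed 2 alone reproduces its record
  r3 <- runExperiment(validateConfig(config = .fastConfig(seeds = 2)),
                      verbose = FALSE)
  expect_equal(r3$overlay[, -1], r1$overlay[r1$overlay$seed == 2, -1],
               ignore_attr = TRUE)
})

test_that("reports and artifacts are written and re-readable", {
  dir <- withr::local_tempdir()
  rep <- runExperiment(validateConfig(config = .fastConfig(seeds = 1)),
                       outputDir = dir, verbose = FALSE)
  expect_true(file.exists(file.path(dir, "report.json")))
  expect_true(file.exists(file.path(dir, "overlay.csv")))
  sd <- file.path(dir, "seed_1")
  expect_true(file.exists(file.path(sd, "ct_intraop.nii.gz")))
  # NIfTI round trip preserves grid geometry and values
  v <- readVolume(file.path(sd, "ct_intraop.nii.gz"))
  rec <- rep$records[["1"]]
  expect_equal(voxelValues(v), voxelValues(rec$volumes$ctIntra),
               tolerance = 1e-6)
  expect_equal(origin(v), origin(rec$volumes$ctIntra), tolerance = 1e-5)
  # transform and mask round trips
  t <- readTransform(file.path(sd, "registration_estimated.txt"))
  expect_equal(transformMatrix(t), transformMatrix(rec$estimated),
               tolerance = 1e-12)
  m <- readMask(file.path(sd, "sln_left_s1_ar.png"))
  expect_identical(maskPixels(m), maskPixels(rec$masks$sln_left$s1))
  # report json is byte-identical across reruns (no timestamps)
  js1 <- readLines(file.path(dir, "report.json"))
  dir2 <- withr::local_tempdir()
  runExperiment(validateConfig(config = .fastConfig(seeds = 1)),
                outputDir = dir2, verbose = FALSE)
  expect_identical(js1, readLines(file.path(dir2, "report.json")))
})

test_that("stage logging reports progress with fingerprints", {
  expect_message(
    runExperiment(validateConfig(config = .fastConfig(seeds = 1)),
                  verbose = TRUE),
    "fingerprint")
})

test_that("registration stays sub-voxel across misalignment bound levels", {
  # medians over matched seeds at three bound levels: the error must
  # never degrade beyond the sub-voxel localization noise floor (half
  # a CT voxel here), and larger bounds must not help
  meds <- vapply(list(c(2, 4), c(5, 10), c(10, 20)), function(b) {
    cfg <- validateConfig(config = list(
      ct = list(voxel_size = 2),
      misalignment = list(max_rotation_deg = b[1],
                          max_translation_mm = b[2], seeds = 1:5),
      registration = list(refine = FALSE),
      overlay = list(upsample = 4)))
    rep <- runExperiment(cfg, verbose = FALSE)
    median(vapply(Filter(function(r) is.null(r$error), rep$records),
                  function(r) max(r$tre), numeric(1)))
  }, numeric(1))
  expect_true(all(meds <= 4.4))        # within one SPECT voxel
  expect_gte(meds[2] + 1.0, meds[1])   # half a CT voxel of slack
  expect_gte(meds[3] + 1.0, meds[2])
})
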