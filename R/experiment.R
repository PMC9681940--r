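#' @include AllClasses.R phantom.R segmentation.R registration.R camera.R metrics.R io.R
NULL

#' Default experiment configuration
#'
#' The study conditions of the default end-to-end experiment: 8/15 mm
#' SLN spheres, CT at 1 mm voxels with sigma = 10 noise, SPECT at
#' 4.4 mm voxels with a 10 mm FWHM PSF and Poisson counting noise,
#' rigid misalignments bounded by 10 degrees / 20 mm over 20 seeds,
#' fiducial-initialized mutual-information registration, and the
#' default downward-looking endoscope camera.
#'
#' @return nested named list; see [validateConfig()] for the schema.
#' @export
defaultConfig <- function() {
  list(
    phantom = list(
      sln_left_diameter = 8, sln_right_diameter = 15,
      field_of_view = c(180, 140, 110),
      sln_centers = NULL, fiducials = NULL, fiducial_radius = NULL),
    ct = list(voxel_size = 1, noise_sigma = 10),
    spect = list(voxel_size = 4.4, activity = 12, psf_fwhm = 10,
                 poisson_scale = 40),
    misalignment = list(max_rotation_deg = 10, max_translation_mm = 20,
                        seeds = 1:20),
    registration = list(init = "fiducial", refine = TRUE, n_bins = 32,
                        levels = 2, init_step = 0.5, max_eval = 150),
    camera = list(distance = 245, focal_length = 1000,
                  image_size = c(1280, 720)),
    overlay = list(upsample = 2, hotspot_fraction = 0.15),
    output_dir = NULL)
}

.checkConfig <- function(cfg) {
  bad <- character()
  chk <- function(ok, msg) if (!isTRUE(all(ok))) bad <<- c(bad, msg)
  chk(cfg$phantom$sln_left_diameter > 0,
      "phantom.sln_left_diameter must be > 0")
  chk(cfg$phantom$sln_right_diameter > 0,
      "phantom.sln_right_diameter must be > 0")
  chk(length(cfg$phantom$field_of_view) == 3 &&
        all(cfg$phantom$field_of_view > 0),
      "phantom.field_of_view must be 3 positive numbers")
  chk(cfg$ct$voxel_size > 0, "ct.voxel_size must be > 0")
  chk(cfg$ct$noise_sigma >= 0, "ct.noise_sigma must be >= 0")
  chk(cfg$spect$voxel_size > 0, "spect.voxel_size must be > 0")
  chk(cfg$spect$activity >= 0, "spect.activity must be >= 0")
  chk(cfg$spect$psf_fwhm >= 0, "spect.psf_fwhm must be >= 0")
  chk(cfg$spect$poisson_scale >= 0, "spect.poisson_scale must be >= 0")
  chk(cfg$misalignment$max_rotation_deg >= 0,
      "misalignment.max_rotation_deg must be >= 0")
  chk(cfg$misalignment$max_translation_mm >= 0,
      "misalignment.max_translation_mm must be >= 0")
  chk(length(cfg$misalignment$seeds) >= 1,
      "misalignment.seeds must list at least one seed")
  chk(cfg$registration$init %in% c("fiducial", "center"),
      "registration.init must be \"fiducial\" or \"center\"")
  chk(cfg$registration$n_bins >= 2, "registration.n_bins must be >= 2")
  chk(all(cfg$registration$levels >= 1),
      "registration.levels must be integers >= 1")
  chk(cfg$camera$distance > 0, "camera.distance must be > 0")
  chk(cfg$camera$focal_length > 0, "camera.focal_length must be > 0")
  chk(cfg$overlay$upsample >= 1, "overlay.upsample must be >= 1")
  chk(cfg$overlay$hotspot_fraction > 0 && cfg$overlay$hotspot_fraction < 1,
      "overlay.hotspot_fraction must be in (0, 1)")
  if (length(bad))
    stop("invalid configuration:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  cfg
}

.mergeConfig <- function(defaults, user, path = character()) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    pre <- if (length(path)) paste0(paste(path, collapse = "."), ".") else ""
    stop("unknown configuration key(s): ",
         paste0(pre, unknown, collapse = ", "), call. = FALSE)
  }
  for (nm in names(user)) {
    if (is.null(user[[nm]])) next  # null means "keep the default"
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- .mergeConfig(defaults[[nm]], as.list(user[[nm]]),
                                     c(path, nm))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load, default-fill and validate an experiment configuration
#'
#' Reads a JSON configuration (an empty file means "all defaults"),
#' merges it over [defaultConfig()], rejects unknown keys, and checks
#' every invariant, reporting all violations at once. `writeConfig`
#' writes the echoed configuration back as JSON; a written-then-reread
#' configuration is identical.
#'
#' @param path JSON file path (optional if `config` is given).
#' @param config configuration as a named list (overrides on defaults).
#' @return the validated, fully defaulted configuration list.
#' @export
validateConfig <- function(path = NULL, config = NULL) {
  if (!is.null(path)) {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    config <- if (nzchar(trimws(txt)))
      jsonlite::fromJSON(txt, simplifyMatrix = TRUE) else list()
  }
  if (is.null(config)) config <- list()
  cfg <- .mergeConfig(defaultConfig(), config)
  .checkConfig(cfg)
}

#' @rdname validateConfig
#' @export
writeConfig <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

.specFromConfig <- function(cfg) {
  spec <- defaultPhantomSpec(cfg$phantom$sln_left_diameter,
                             cfg$phantom$sln_right_diameter,
                             cfg$phantom$field_of_view)
  if (!is.null(cfg$phantom$sln_centers))
    spec@slnCenters <- matrix(as.numeric(cfg$phantom$sln_centers), 2, 3)
  if (!is.null(cfg$phantom$fiducials))
    spec@fiducials <- matrix(as.numeric(cfg$phantom$fiducials), ncol = 3)
  if (!is.null(cfg$phantom$fiducial_radius))
    spec@fiducialRadius <- cfg$phantom$fiducial_radius
  validObject(spec)
  spec
}

.log <- function(verbose, stage, t0, ...) {
  if (!verbose) return(invisible())
  message(sprintf("[%s] %s (%.2fs)", stage, paste0(...),
                  as.numeric(proc.time()[3]) - t0))
}

# One seed of the end-to-end experiment. Returns a record list.
.runSeed <- function(seed, labelmap, spec, ctM, spM, cam, cfg,
                     oracle = FALSE, verbose = FALSE) {
  t0 <- as.numeric(proc.time()[3])
  bounds <- cfg$misalignment
  tTrue <- sampleRigidMisalignment(bounds$max_rotation_deg,
                                   bounds$max_translation_mm,
                                   .stageSeed(seed, 1),
                                   center = spec@fieldOfView / 2)
  ctIntra <- renderCT(labelmap, ctM, identityTransform(), .stageSeed(seed, 2))
  ctPre <- renderCT(labelmap, ctM, tTrue, .stageSeed(seed, 3))
  spectPre <- renderSPECT(labelmap, spM, tTrue, .stageSeed(seed, 4))
  .log(verbose, sprintf("seed %d", seed), t0,
       sprintf("rendered CT/SPECT (fingerprints %.6g / %.6g / %.6g)",
               sum(ctIntra@values), sum(ctPre@values), sum(spectPre@values)))
  trueT <- invertTransform(tTrue)  # preop-session world -> intraop world

  fidFix <- detectFiducials(ctIntra, spec@fiducials)
  fidMov <- detectFiducials(ctPre, spec@fiducials)
  fidReg <- registerPoints(fidMov, fidFix)

  regCfg <- cfg$registration
  if (oracle) {
    est <- trueT
    miMetric <- NA_real_; converged <- TRUE; nEval <- 0L
  } else {
    init <- if (regCfg$init == "fiducial") fidReg$transform
            else centerInit(ctIntra, ctPre)
    if (isTRUE(regCfg$refine)) {
      mi <- registerRigidMI(ctIntra, ctPre, init, nBins = regCfg$n_bins,
                            levels = as.integer(regCfg$levels),
                            initStep = regCfg$init_step,
                            maxEval = as.integer(regCfg$max_eval))
      est <- mi$transform
      miMetric <- mi$finalMetric; converged <- mi$converged
      nEval <- mi$nEvaluations
    } else {
      est <- init
      miMetric <- NA_real_; converged <- TRUE; nEval <- 0L
    }
  }
  targets <- applyTransform(tTrue, spec@slnCenters)
  tre <- targetRegistrationError(est, trueT, targets)
  .log(verbose, sprintf("seed %d", seed), t0,
       sprintf("registered: FRE %.4f mm, TRE %.4f / %.4f mm",
               fidReg$fre, tre[1], tre[2]))

  segPre <- segmentCT(ctPre)
  hot <- segmentSpectHotspots(spectPre, cfg$overlay$hotspot_fraction)
  hotDist <- sqrt(rowSums((centroids(hot)[c("sln_left", "sln_right"), ] -
    centroids(segPre)[c("sln_left", "sln_right"), ])^2))

  rows <- list()
  masks <- list()
  for (side in c("sln_left", "sln_right")) {
    seg <- .refineVolume(.cropToMask(maskVolume(segPre, side)),
                         as.integer(cfg$overlay$upsample))
    pair <- makeOverlayPair(cam, seg, est, trueT)
    rows[[side]] <- overlayReport(pair$s1, pair$s2,
                                  side = sub("sln_", "", side))
    masks[[side]] <- pair
  }
  overlay <- do.call(rbind, rows)
  rownames(overlay) <- NULL
  .log(verbose, sprintf("seed %d", seed), t0,
       sprintf("overlay: ratio %.4f / %.4f, coverage %.2f%% / %.2f%%",
               overlay$ratio[1], overlay$ratio[2],
               100 * overlay$coverage[1], 100 * overlay$coverage[2]))
  list(seed = seed, true = tTrue, trueInverse = trueT, estimated = est,
       fre = fidReg$fre, tre = stats::setNames(tre, c("left", "right")),
       mi = miMetric, converged = converged, nEvaluations = nEval,
       hotspotAgreement = stats::setNames(hotDist, c("left", "right")),
       overlay = overlay,
       volumes = list(ctIntra = ctIntra, ctPre = ctPre, spectPre = spectPre),
       masks = masks)
}

#' Run the full fusion experiment
#'
#' For each seed: draw a bounded rigid misalignment, render the
#' intraoperative CT (identity pose) and the preoperative CT + SPECT
#' (misaligned pose, hybrid co-registered), segment all target
#' structures, register the sessions (closed-form fiducial
#' initialization refined by mutual information between the two CT
#' volumes), confirm the SLNs against the SPECT hotspots, render the
#' AR (estimated transform) and ground-truth (true transform) mask per
#' SLN through the pinhole camera, and score the overlay. A failing
#' seed is recorded and the run continues; the report aggregates
#' medians and IQRs over the successful seeds.
#'
#' In `oracle` mode the registration is bypassed with the true
#' transform, so every coverage is exactly 1 and every ratio exactly 0
#' (the perfect-alignment limit used as a pipeline self-check).
#'
#' @param config configuration list (see [defaultConfig()]) or the
#'   result of [validateConfig()].
#' @param oracle logical; bypass registration with the true transform.
#' @param outputDir if non-NULL, write volumes (NIfTI), transforms
#'   (plain-text 4x4), masks (PNG) and reports (JSON + CSV) there.
#' @param verbose print stage logs with timings and fingerprints.
#' @return an `ExperimentReport` list with elements `records` (one per
#'   seed), `overlay` (per-seed per-SLN data.frame), `aggregate`,
#'   `errors` and `config`.
#' @examples
#' \donttest{
#' cfg <- validateConfig(config = list(misalignment = list(seeds = 1:2)))
#' rep <- runExperiment(cfg, verbose = FALSE)
#' rep$aggregate
#' }
#' @export
runExperiment <- function(config = defaultConfig(), oracle = FALSE,
                          outputDir = NULL, verbose = TRUE) {
  cfg <- validateConfig(config = config)
  if (is.null(outputDir)) outputDir <- cfg$output_dir
  t0 <- as.numeric(proc.time()[3])
  spec <- .specFromConfig(cfg)
  ctM <- ctModel(cfg$ct$voxel_size, cfg$ct$noise_sigma)
  spM <- spectModel(cfg$spect$voxel_size, cfg$spect$activity,
                    cfg$spect$psf_fwhm, cfg$spect$poisson_scale)
  cam <- defaultCamera(spec, cfg$camera$distance, cfg$camera$focal_length,
                       cfg$camera$image_size)
  labelmap <- buildPhantomLabelMap(spec, ctM@voxelSize)
  .log(verbose, "setup", t0,
       sprintf("phantom voxelized: %s voxels, fingerprint %.6g",
               paste(dim(labelmap@values), collapse = "x"),
               sum(labelmap@values)))
  records <- list()
  errors <- list()
  for (seed in cfg$misalignment$seeds) {
    rec <- tryCatch(
      .runSeed(seed, labelmap, spec, ctM, spM, cam, cfg,
               oracle = oracle, verbose = verbose),
      error = function(e) {
        warning("seed ", seed, " failed: ", conditionMessage(e),
                call. = FALSE)
        list(seed = seed, error = conditionMessage(e))
      })
    records[[as.character(seed)]] <- rec
    if (!is.null(outputDir) && is.null(rec$error))
      .writeSeedOutputs(rec, outputDir)
  }
  ok <- Filter(function(r) is.null(r$error), records)
  errors <- Filter(function(r) !is.null(r$error), records)
  if (length(ok) == 0)
    stop("all seeds failed; first error: ", errors[[1]]$error)
  overlay <- do.call(rbind, lapply(ok, function(r)
    cbind(seed = r$seed, r$overlay)))
  rownames(overlay) <- NULL
  aggr <- .aggregateReport(ok, overlay)
  report <- list(records = records, overlay = overlay, aggregate = aggr,
                 errors = lapply(errors, function(r)
                   list(seed = r$seed, message = r$error)),
                 config = cfg)
  class(report) <- "ExperimentReport"
  if (!is.null(outputDir)) writeExperimentReport(report, outputDir)
  .log(verbose, "done", t0,
       sprintf("%d/%d seeds succeeded", length(ok), length(records)))
  report
}

.iqr <- function(x) unname(diff(quantile(x, c(0.25, 0.75), names = FALSE)))

.aggregateReport <- function(ok, overlay) {
  bySide <- function(col, side, f)
    f(overlay[[col]][overlay$side == side])
  tre <- do.call(rbind, lapply(ok, `[[`, "tre"))
  list(
    n_seeds = length(ok),
    ratio = list(
      left = list(median = bySide("ratio", "left", median),
                  iqr = bySide("ratio", "left", .iqr)),
      right = list(median = bySide("ratio", "right", median),
                   iqr = bySide("ratio", "right", .iqr))),
    coverage = list(
      left = list(median = bySide("coverage", "left", median),
                  iqr = bySide("coverage", "left", .iqr)),
      right = list(median = bySide("coverage", "right", median),
                   iqr = bySide("coverage", "right", .iqr))),
    tre_mm = list(
      left = list(median = median(tre[, "left"]), iqr = .iqr(tre[, "left"])),
      right = list(median = median(tre[, "right"]), iqr = .iqr(tre[, "right"]))),
    fre_mm = list(median = median(vapply(ok, `[[`, numeric(1), "fre")),
                  iqr = .iqr(vapply(ok, `[[`, numeric(1), "fre"))))
}

#' @export
print.ExperimentReport <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("ExperimentReport: %d seeds (%d failed)\n",
              a$n_seeds + length(x$errors), length(x$errors)))
  cat(sprintf("  normalized barycenter distance (median): left %.4f, right %.4f\n",
              a$ratio$left$median, a$ratio$right$median))
  cat(sprintf("  coverage rate (median):                  left %.2f%%, right %.2f%%\n",
              100 * a$coverage$left$median, 100 * a$coverage$right$median))
  cat(sprintf("  SLN target registration error (median):  left %.4f mm, right %.4f mm\n",
              a$tre_mm$left$median, a$tre_mm$right$median))
  cat(sprintf("  fiducial registration error (median):    %.4f mm\n",
              a$fre_mm$median))
  invisible(x)
}
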