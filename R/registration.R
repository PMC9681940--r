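#' @include AllClasses.R volume.R transforms.R
NULL

#' Mutual information of two images on a common grid
#'
#' Shannon mutual information in bits from the dense joint intensity
#' histogram: `MI = sum p(a,b) log2[p(a,b) / (p(a) p(b))]`. Each image
#' is min-max normalized over the evaluated voxels and binned into
#' `nBins` equal-width bins. Voxels with a non-finite value in either
#' image are excluded (resampling marks out-of-field voxels `NA`), as
#' are voxels outside `mask`.
#'
#' @param fixed,moving [Volume3D-class] objects (or plain arrays) on
#'   the same grid.
#' @param nBins number of histogram bins per axis (>= 2).
#' @param mask optional logical array selecting voxels to use.
#' @return Mutual information in bits (>= 0). A constant image is
#'   degenerate: the function warns and returns 0.
#' @examples
#' a <- array(rep(c(0, 1), 500), c(10, 10, 10))
#' mutualInformation(a, a)  # 1 bit: MI(A, A) = H(A)
#' @export
mutualInformation <- function(fixed, moving, nBins = 32L, mask = NULL) {
  f <- if (is(fixed, "Volume3D")) fixed@values else fixed
  m <- if (is(moving, "Volume3D")) moving@values else moving
  if (!identical(dim(f), dim(m)))
    stop("fixed and moving must share a grid")
  if (nBins < 2) stop("nBins must be >= 2")
  keep <- is.finite(f) & is.finite(m)
  if (!is.null(mask)) keep <- keep & mask
  f <- f[keep]; m <- m[keep]
  if (length(f) == 0) stop("no voxels to evaluate")
  rf <- range(f); rm_ <- range(m)
  if (rf[1] == rf[2] || rm_[1] == rm_[2]) {
    warning("constant image: mutual information is degenerate (0)")
    return(0)
  }
  bf <- pmin(nBins - 1L, as.integer((f - rf[1]) / (rf[2] - rf[1]) * nBins))
  bm <- pmin(nBins - 1L, as.integer((m - rm_[1]) / (rm_[2] - rm_[1]) * nBins))
  joint <- tabulate(1L + bf + nBins * bm, nbins = nBins * nBins)
  p <- joint / sum(joint)
  dim(p) <- c(nBins, nBins)
  pf <- rowSums(p); pm <- colSums(p)
  nz <- which(p > 0, arr.ind = TRUE)
  pv <- p[nz]
  max(0, sum(pv * log2(pv / (pf[nz[, 1]] * pm[nz[, 2]]))))
}

#' Closed-form rigid registration of matched point sets
#'
#' Least-squares rigid alignment (centroid alignment followed by
#' orthogonal Procrustes via SVD, with det +1 enforced so a
#' reflection-only optimum is folded back to a proper rotation and
#' logged). The fiducial registration error (FRE) is the root mean
#' square residual after alignment.
#'
#' @param movingPts,fixedPts N x 3 matrices (N >= 3) of matched points
#'   in mm; `movingPts[k, ]` corresponds to `fixedPts[k, ]`.
#' @return list with elements `transform` ([RigidTransform-class],
#'   moving -> fixed), `fre` (mm), `converged`, `nEvaluations`,
#'   `finalMetric` (NA; no image metric involved).
#' @examples
#' pts <- rbind(c(0,0,0), c(10,0,0), c(0,10,0), c(0,0,10))
#' t <- rigidTransformFromParams(c(5, -3, 10), c(4, 2, -1))
#' registerPoints(pts, applyTransform(t, pts))$fre  # ~ 0
#' @export
registerPoints <- function(movingPts, fixedPts) {
  if (is.null(dim(movingPts)) || is.null(dim(fixedPts)) ||
      !all(dim(movingPts) == dim(fixedPts)) || ncol(movingPts) != 3)
    stop("point sets must be matched N x 3 matrices")
  n <- nrow(movingPts)
  if (n < 3) stop("at least 3 matched pairs are required")
  mc <- colMeans(movingPts); fc <- colMeans(fixedPts)
  X <- sweep(movingPts, 2, mc); Y <- sweep(fixedPts, 2, fc)
  sv <- svd(crossprod(X, Y))  # H = X^T Y
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-300))
    stop("points are collinear: rotation is not determined")
  d <- det(sv$v %*% t(sv$u))
  if (d < 0)
    message("registerPoints: reflection optimum corrected to a proper rotation")
  R <- sv$v %*% diag(c(1, 1, sign(d))) %*% t(sv$u)
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- fc - R %*% mc
  transform <- rigidTransform(m)
  res <- applyTransform(transform, movingPts) - fixedPts
  list(transform = transform, fre = sqrt(mean(rowSums(res^2))),
       converged = TRUE, nEvaluations = 0L, finalMetric = NA_real_)
}

#' Translation-only initialization from intensity centroids
#'
#' Aligns the intensity-weighted centres of mass of the two volumes
#' (values shifted to be non-negative before weighting); a cheap
#' stand-in for the study's initial manual alignment when no fiducials
#' are available.
#'
#' @param fixed,moving [Volume3D-class] objects.
#' @return A translation-only [RigidTransform-class] (moving -> fixed).
#' @export
centerInit <- function(fixed, moving) {
  com <- function(v) {
    w <- v@values - min(v@values)
    idx <- arrayInd(seq_along(w), dim(v@values)) - 1
    as.numeric(voxelToWorld(v, colSums(idx * as.numeric(w)) / sum(w)))
  }
  m <- diag(4)
  m[1:3, 4] <- com(fixed) - com(moving)
  rigidTransform(m)
}

# Build the 6-parameter transform (rotations deg about `center`,
# then translation) composed with the initial transform.
.paramTransform <- function(p, center, init) {
  composeTransforms(
    rigidTransformFromParams(p[1:3], p[4:6], center = center), init)
}

#' Rigid registration by mutual-information maximization
#'
#' Coarse-to-fine 6-DOF registration maximizing the mutual information
#' of `moving` resampled onto the (block-mean downsampled) fixed grid.
#' Optimization is derivative-free Nelder-Mead per pyramid level,
#' parameterized as rotations (degrees) about the fixed-volume centre
#' plus translations (mm), always composed with `init`; the initial
#' simplex step per level is set by `initStep`. The best parameters
#' seen (including the initialization itself, which is part of the
#' initial simplex) are carried to the next level, so the returned
#' transform never has lower mutual information at the finest level
#' than the initialization.
#'
#' @param fixed,moving [Volume3D-class] images (non-constant).
#' @param init initial [RigidTransform-class] (moving -> fixed world),
#'   e.g. from [registerPoints()] on fiducials or [centerInit()].
#' @param nBins histogram bins per axis for [mutualInformation()].
#' @param levels integer downsampling factors of the fixed grid,
#'   coarse to fine.
#' @param initStep initial Nelder-Mead step per level (deg / mm).
#' @param maxEval Nelder-Mead iteration budget per level.
#' @return list with `transform`, `finalMetric` (bits, finest level),
#'   `converged`, `nEvaluations`, `fre` (NA), `params` (the 6-vector
#'   relative to `init`).
#' @export
registerRigidMI <- function(fixed, moving, init = identityTransform(),
                            nBins = 32L, levels = c(4L, 2L, 1L),
                            initStep = c(4, 1, 0.25),
                            maxEval = c(400L, 200L, 120L)) {
  if (length(initStep) == 1L) initStep <- rep(initStep, length(levels))
  if (length(maxEval) == 1L) maxEval <- rep(maxEval, length(levels))
  stopifnot(length(initStep) == length(levels),
            length(maxEval) == length(levels))
  for (v in list(fixed, moving))
    if (max(v@values) == min(v@values))
      stop("degenerate input: constant image cannot drive mutual information")
  centre <- as.numeric(voxelToWorld(fixed, (dim(fixed@values) - 1) / 2))
  p <- rep(0, 6)
  nEval <- 0L
  conv <- TRUE
  finalMetric <- NA_real_
  for (li in seq_along(levels)) {
    fx <- .downsampleVolume(fixed, as.integer(levels[li]))
    negMI <- function(par) {
      mv <- resampleVolume(moving, .paramTransform(par, centre, init), fx,
                           "linear", fill = NA_real_)
      -suppressWarnings(mutualInformation(fx, mv, nBins = nBins))
    }
    opt <- optim(p, negMI, method = "Nelder-Mead",
                 control = list(maxit = maxEval[li],
                                parscale = rep(initStep[li] / 0.1, 6),
                                reltol = 1e-9))
    p <- opt$par
    bestVal <- opt$value
    nEval <- nEval + opt$counts[["function"]]
    if (li == length(levels)) {
      # guard: coarse levels optimize a different (downsampled) metric,
      # so re-check the plain initialization on the finest grid
      atInit <- negMI(rep(0, 6))
      nEval <- nEval + 1L
      if (atInit < bestVal) {
        p <- rep(0, 6)
        bestVal <- atInit
      }
      conv <- opt$convergence == 0
      finalMetric <- -bestVal
    }
  }
  list(transform = .paramTransform(p, centre, init),
       finalMetric = finalMetric, converged = conv,
       nEvaluations = as.integer(nEval), fre = NA_real_, params = p)
}

#' Target registration error
#'
#' Distance `||estimated(x) - true(x)||` per target point, in mm: how
#' far the estimated transform displaces each clinically relevant
#' target from where the true transform puts it. Quantifies what the
#' study assessed by visual validation on bone structures.
#'
#' @param estimated,true [RigidTransform-class] objects (same
#'   direction convention).
#' @param targets N x 3 matrix (or numeric(3)) of target points in the
#'   moving-session world frame, mm.
#' @return numeric vector of per-target errors (mm).
#' @export
targetRegistrationError <- function(estimated, true, targets) {
  if (is.null(dim(targets))) targets <- matrix(targets, 1)
  if (nrow(targets) == 0) stop("empty target list")
  d <- applyTransform(estimated, targets) - applyTransform(true, targets)
  sqrt(rowSums(d^2))
}
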