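#' @include AllClasses.R io.R
NULL

# Default ellipsoidal mask on a small grid: ~half the box is in-mask, mirror
# symmetric about the first axis.
defaultMask <- function(dims = c(16L, 16L, 12L), voxelSize = c(2.2, 2.2, 2.2)) {
  d <- as.integer(dims)
  cx <- (d + 1) / 2
  arr <- array(0, d)
  idx <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                               z = seq_len(d[3])))
  rad <- (idx[, 1] - cx[1])^2 / (d[1] / 2)^2 +
         (idx[, 2] - cx[2])^2 / (d[2] / 2)^2 +
         (idx[, 3] - cx[3])^2 / (d[3] / 2)^2
  arr[idx[rad <= 1, , drop = FALSE]] <- 1
  gridMask(arr, voxelSize = voxelSize, mirror = TRUE)
}

# Bilateral Gaussian blob map over the mask: a bump at `centre` (lattice
# coordinates in the left half) mirrored about the first-axis mid-plane.
bilateralBlob <- function(mask, centre, sigmaVox = 1.6, bilateral = TRUE) {
  co <- mask@coords
  bump <- function(cen) {
    d2 <- (co[, 1] - cen[1])^2 + (co[, 2] - cen[2])^2 + (co[, 3] - cen[3])^2
    exp(-d2 / (2 * sigmaVox^2))
  }
  v <- bump(centre)
  if (bilateral)
    v <- pmax(v, bump(c(mask@dims[1] + 1 - centre[1], centre[2], centre[3])))
  v[v < 1e-3] <- 0
  v
}

#' Ground-truth specification for a synthetic developmental cohort
#'
#' Defaults emulate the statistical structure the maturational-network method
#' assumes: P = 5 bilateral mirror-symmetric network maps on a small
#' ellipsoidal grid (~1,500 in-mask voxels), latent network timecourses whose
#' pairwise couplings increase linearly with age on two declared "emerging"
#' edges (networks 1-2 and 3-4; network 5 stays static), spatially
#' autocorrelated noise whose kernel width shrinks with age (the common-space
#' smearing of smaller, younger brains), and an optional motion factor weakly
#' anti-correlated with age (target r = -0.25).
#'
#' @param mask a [GridMask-class]; default small ellipsoid, mirror-paired.
#' @param nNetworks number of planted networks P (default 5).
#' @param emergingEdges 2-column matrix of network index pairs whose coupling
#'   grows with age; default rbind(c(1,2), c(3,4)).
#' @param couplingSlopeValue per-week correlation increment on emerging edges
#'   (default 0.045: coupling grows from ~0 to ~0.6 over 25-38 weeks).
#' @param baselineCoupling P x P age-independent latent correlation matrix
#'   (default identity: networks uncorrelated at the reference age).
#' @param ageRef age at which the latent covariance equals the baseline
#'   (default 25 weeks).
#' @param noiseSd marginal sd of the additive voxel noise (default 0.5;
#'   network amplitude is ~1 at blob cores).
#' @param smearFwhm c(young, old) noise-smearing FWHM in mm at
#'   `smearAgeRange` (default c(6, 3): twice the smear at 25w as at 38w,
#'   tracking the ~3-fold volume growth over the period).
#' @param smearAgeRange ages anchoring the smear interpolation
#'   (default c(25, 38)).
#' @param smearSignal also smear the network maps per subject
#'   (peak-preserving), emulating common-space blurring of the signal itself
#'   (default FALSE).
#' @param motionTargetR target correlation between age and the latent motion
#'   factor (default -0.25; NA disables motion simulation).
#' @param blobSigmaVox spatial sd of the network blobs in voxels.
#' @return a validated [TruthSpec-class].
#' @export
truthSpec <- function(mask = defaultMask(), nNetworks = 5L,
                      emergingEdges = rbind(c(1L, 2L), c(3L, 4L)),
                      couplingSlopeValue = 0.045,
                      baselineCoupling = diag(nNetworks),
                      ageRef = 25, noiseSd = 0.5,
                      smearFwhm = c(6, 3), smearAgeRange = c(25, 38),
                      smearSignal = FALSE, motionTargetR = -0.25,
                      blobSigmaVox = 1.3) {
  d <- mask@dims
  # Deterministic blob centres (fractions of the grid) in the left half,
  # spaced so that network supports stay essentially disjoint after
  # mirroring (pairwise min-map overlap ~0.1 at the default blob width):
  # a planted "static" network must not share territory with an emerging one.
  centreTable <- rbind(
    c(0.25, 0.25, 0.25), c(0.25, 0.80, 0.25), c(0.25, 0.25, 0.85),
    c(0.25, 0.80, 0.85), c(0.25, 0.525, 0.55), c(0.38, 0.40, 0.55),
    c(0.38, 0.70, 0.55), c(0.25, 0.55, 0.85))
  if (nNetworks > nrow(centreTable))
    stop("at most ", nrow(centreTable), " default networks; pass maps directly")
  mapsList <- lapply(seq_len(nNetworks), function(i) {
    cen <- round(centreTable[i, ] * d)
    bilateralBlob(mask, cen, sigmaVox = blobSigmaVox)
  })
  nm <- do.call(rbind, mapsList)
  slope <- matrix(0, nNetworks, nNetworks)
  for (e in seq_len(nrow(emergingEdges))) {
    i <- emergingEdges[e, 1]; j <- emergingEdges[e, 2]
    slope[i, j] <- slope[j, i] <- couplingSlopeValue
  }
  new("TruthSpec", networkMaps = nm, baselineCoupling = baselineCoupling,
      couplingSlope = slope, ageRef = ageRef, noiseSd = noiseSd,
      smearFwhm = as.numeric(smearFwhm),
      smearAgeRange = as.numeric(smearAgeRange),
      smearSignal = smearSignal, motionTargetR = motionTargetR,
      mask = mask)
}

# latent covariance at a given age; error if not positive definite
latentSigma <- function(spec, age) {
  s <- spec@baselineCoupling + spec@couplingSlope * (age - spec@ageRef)
  ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("specification error: latent covariance not positive definite at age ",
         format(age, digits = 4))
  s
}

# noise smearing FWHM (mm) at a given age: linear, monotone non-increasing
smearFwhmAt <- function(spec, age) {
  a <- spec@smearAgeRange
  f <- spec@smearFwhm
  w <- (age - a[1]) / (a[2] - a[1])
  w <- min(max(w, 0), 1)
  f[1] + w * (f[2] - f[1])
}

# Smear full-grid white noise (prod(dims) x T, column-major volumes) and
# return the in-mask N x T matrix with marginal sd exactly 1 per voxel:
# smoothing changes only the autocorrelation, never the variance, so no
# artifactual age effect enters through kernel truncation at volume edges.
# For white unit input the smoothed variance is the separable product of the
# squared kernel row sums.
smearNoise <- function(noiseFull, mask, fwhm) {
  d <- mask@dims
  lin <- (mask@coords[, 3] - 1L) * (d[1] * d[2]) +
         (mask@coords[, 2] - 1L) * d[1] + mask@coords[, 1]
  if (fwhm <= 0) return(noiseFull[lin, , drop = FALSE])
  sig <- fwhmToSigmaVox(fwhm, mask@voxelSize)
  v1 <- rowSums(gaussConvMatrix(d[1], sig[1])^2)
  v2 <- rowSums(gaussConvMatrix(d[2], sig[2])^2)
  v3 <- rowSums(gaussConvMatrix(d[3], sig[3])^2)
  sdVec <- sqrt(outer(outer(v1, v2), v3))[mask@coords]
  out <- matrix(NA_real_, length(lin), ncol(noiseFull))
  for (t in seq_len(ncol(noiseFull))) {
    vol <- smoothVolume(array(noiseFull[, t], d), sig)
    out[, t] <- vol[mask@coords] / sdVec
  }
  out
}

#' Generate a synthetic cohort with known ground truth
#'
#' Latent-first generation: per subject, P network timecourses are drawn with
#' covariance `baseline + slope * (age_s - ageRef)` (positive definiteness is
#' checked at every sampled age), projected through the ground-truth spatial
#' maps, and white noise smeared with the subject's age-dependent Gaussian
#' kernel is added. With `smearSignal = TRUE` the maps themselves are smeared
#' per subject (peak-preserving) before projection. Fully reproducible from
#' (spec, K, T, ages, seed).
#'
#' @param spec a [TruthSpec-class].
#' @param K number of subjects (>= 3).
#' @param T_ timepoints per subject (>= 50; default 350, a typical fetal
#'   resting-state acquisition length).
#' @param ages optional numeric length-K gestational ages; default evenly
#'   spread over 25-38 weeks.
#' @param seed integer seed.
#' @param nMotionParams,nMotionStacks motion trace dimensions (defaults 6
#'   parameters x 16 stacks) used when `spec@motionTargetR` is not NA.
#' @return a list with `cohort` ([CohortTable-class], motion traces attached
#'   when simulated), `series` (list of [MaskedSeries-class]), `spec` (the
#'   truth), and `motionFactor` (the latent per-subject motion factor, or
#'   NULL).
#' @export
generateCohort <- function(spec, K, T_ = 350L, ages = NULL, seed = 1L,
                           nMotionParams = 6L, nMotionStacks = 16L) {
  stopifnot(is(spec, "TruthSpec"), K >= 3L, T_ >= 50L)
  if (is.null(ages)) ages <- seq(25, 38, length.out = K)
  if (length(ages) != K) stop("ages must have length K")
  if (diff(range(ages)) <= 0) stop("ages must span a nondegenerate range")
  oldSeed <- globalSeed()
  on.exit(restoreSeed(oldSeed), add = TRUE)
  set.seed(as.integer(seed))

  mask <- spec@mask
  n <- nVoxels(mask)
  p <- nrow(spec@networkMaps)
  for (a in range(ages)) latentSigma(spec, a)   # PD at the extremes up front

  motionFactor <- NULL
  motion <- list()
  if (is.finite(spec@motionTargetR)) {
    za <- (ages - mean(ages)) / stats::sd(ages)
    eps <- stats::rnorm(K)
    eps <- stats::residuals(stats::lm(eps ~ za))
    eps <- eps / stats::sd(eps)
    rho <- spec@motionTargetR
    motionFactor <- rho * za + sqrt(1 - rho^2) * eps
  }
  # per-(parameter, stack) loadings of the one-factor motion model
  motionLoadings <- if (!is.null(motionFactor))
    0.5 + stats::runif(nMotionParams * nMotionStacks) else NULL

  series <- vector("list", K)
  ids <- sprintf("sub-%03d", seq_len(K))
  for (s in seq_len(K)) {
    sig <- latentSigma(spec, ages[s])
    ch <- chol(sig)
    tc <- t(ch) %*% matrix(stats::rnorm(p * T_), p, T_)   # P x T latent
    mapsS <- spec@networkMaps
    if (spec@smearSignal) {
      fw <- smearFwhmAt(spec, ages[s])
      sigv <- fwhmToSigmaVox(fw, mask@voxelSize)
      for (q in seq_len(p)) {
        vol <- smoothVolume(vectorToVolume(mapsS[q, ], mask), sigv)
        v <- volumeToVector(vol, mask)
        peak <- max(v)
        if (peak > 0) v <- v * (max(mapsS[q, ]) / peak)   # preserve the peak
        mapsS[q, ] <- v
      }
    }
    x <- t(mapsS) %*% tc                                   # N x T signal
    noiseFull <- matrix(stats::rnorm(prod(mask@dims) * T_),
                        prod(mask@dims), T_)
    noise <- smearNoise(noiseFull, mask, smearFwhmAt(spec, ages[s]))
    x <- x + spec@noiseSd * noise
    series[[s]] <- new("MaskedSeries", subjectID = ids[s], data = x, tr = 1)
    if (!is.null(motionFactor)) {
      scale <- pmax(1 + 0.3 * motionFactor[s], 0.05)
      incr <- array(stats::rnorm(nMotionParams * nMotionStacks * T_),
                    c(nMotionParams, nMotionStacks, T_))
      incr <- incr * array(motionLoadings * scale,
                           c(nMotionParams, nMotionStacks, T_))
      motion[[ids[s]]] <- aperm(apply(incr, c(1, 2), cumsum), c(2, 3, 1))
    }
  }
  cohort <- cohortTable(ids, ages, motion = motion)
  list(cohort = cohort, series = series, spec = spec,
       motionFactor = motionFactor,
       motionLoadings = motionLoadings)
}

#' Write a generated cohort to disk in standard formats
#'
#' Cohort table as TSV, per-subject series and the binary mask as NIfTI, and
#' a truth manifest (YAML plus ground-truth map NIfTI), so generated data can
#' feed the pipeline exactly like real data.
#'
#' @param generated the list returned by [generateCohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohortData <- function(generated, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mask <- generated$spec@mask
  writeCohort(generated$cohort, file.path(dir, "cohort.tsv"))
  maskArr <- vectorToVolume(rep(1, nVoxels(mask)), mask)
  img <- RNifti::asNifti(maskArr)
  RNifti::pixdim(img) <- mask@voxelSize
  RNifti::writeNifti(img, file.path(dir, "mask.nii.gz"))
  for (s in generated$series)
    writeMaskedSeries(s, mask, file.path(dir, paste0(s@subjectID, ".nii.gz")))
  truth <- new("SpatialMapSet", maps = generated$spec@networkMaps,
               mixing = matrix(0, 0, 0), kind = "truth")
  writeMapSet(truth, mask, file.path(dir, "truth_maps.nii.gz"))
  manifest <- list(
    n_networks = nrow(generated$spec@networkMaps),
    ages = as.numeric(generated$cohort@age),
    noise_sd = generated$spec@noiseSd,
    smear_fwhm = as.numeric(generated$spec@smearFwhm),
    coupling_slope = as.numeric(generated$spec@couplingSlope),
    baseline_coupling = as.numeric(generated$spec@baselineCoupling))
  yaml::write_yaml(manifest, file.path(dir, "truth.yaml"))
  invisible(dir)
}
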