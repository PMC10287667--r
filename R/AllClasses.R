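#' @include utils.R
NULL

#' Cohort table: subjects, gestational ages, optional motion traces
#'
#' Holds the cross-sectional design: one row per subject with gestational age
#' in weeks, plus optional per-subject motion-parameter traces
#' (parameters x stacks x timepoints arrays) used by [fdGlobal()].
#'
#' @slot subjectID character vector of unique subject identifiers.
#' @slot age numeric vector of gestational ages (weeks).
#' @slot motion named list of 3D arrays (parameters x stacks x timepoints),
#'   one per subject, or an empty list.
#' @seealso [readCohort()], [generateCohort()]
#' @export
setClass("CohortTable",
  representation(subjectID = "character", age = "numeric", motion = "list"),
  prototype(motion = list()),
  validity = function(object) {
    msg <- character()
    k <- length(object@subjectID)
    if (k < 3L)
      msg <- c(msg, "need K >= 3 subjects (OLS on [1, age] requires df = K - 2 >= 1)")
    if (anyDuplicated(object@subjectID))
      msg <- c(msg, "subject ids must be unique")
    if (length(object@age) != k)
      msg <- c(msg, "age must have one value per subject")
    if (!all(is.finite(object@age)))
      msg <- c(msg, "ages must be finite")
    else if (stats::var(object@age) <= 0)
      msg <- c(msg, "age variance must be > 0 (degenerate age regressor)")
    if (length(object@motion) &&
        !all(names(object@motion) %in% object@subjectID))
      msg <- c(msg, "motion trace names must match subject ids")
    if (length(msg)) msg else TRUE
  })

#' Brain mask on a shared lattice
#'
#' The single source of truth for voxel order: in-mask voxels are stored in
#' lexicographic order of their (x, y, z) lattice index, and every N-length
#' vector in the package indexes this order.
#'
#' @slot coords integer N x 3 matrix of lattice coordinates (1-based).
#' @slot dims integer length-3 grid dimensions.
#' @slot voxelSize numeric length-3 voxel size in mm.
#' @slot mirrorPair integer length-N index of the homologous contralateral
#'   voxel (an involution), NA where no partner exists.
#' @slot tissue character length-N tissue label ("cortex", "white-matter",
#'   "other") or length-0 when unused.
#' @seealso [gridMask()], [readMask()], [computeMirrorPairs()]
#' @export
setClass("GridMask",
  representation(coords = "matrix", dims = "integer",
                 voxelSize = "numeric", mirrorPair = "integer",
                 tissue = "character"),
  prototype(mirrorPair = integer(), tissue = character()),
  validity = function(object) {
    msg <- character()
    n <- nrow(object@coords)
    if (n == 0L) msg <- c(msg, "mask must contain at least one voxel")
    if (ncol(object@coords) != 3L) msg <- c(msg, "coords must be N x 3")
    if (anyDuplicated(object@coords)) msg <- c(msg, "voxel coordinates must be unique")
    if (length(object@dims) != 3L || length(object@voxelSize) != 3L)
      msg <- c(msg, "dims and voxelSize must have length 3")
    if (n > 0L && (any(object@coords < 1L) ||
        any(object@coords > matrix(object@dims, n, 3, byrow = TRUE))))
      msg <- c(msg, "voxel coordinates outside grid bounds")
    mp <- object@mirrorPair
    if (length(mp)) {
      if (length(mp) != n) msg <- c(msg, "mirrorPair must have length N")
      ok <- !is.na(mp)
      if (any(mp[ok] < 1L | mp[ok] > n))
        msg <- c(msg, "mirrorPair indices out of range")
      else if (!all(mp[mp[ok]] == which(ok)))
        msg <- c(msg, "mirrorPair must be an involution")
    }
    if (length(object@tissue) && length(object@tissue) != n)
      msg <- c(msg, "tissue must have length N when present")
    if (length(msg)) msg else TRUE
  })

#' One subject's masked voxel-by-time series
#'
#' @slot subjectID character scalar.
#' @slot data numeric N voxels x T timepoints matrix, in mask voxel order.
#' @slot tr numeric repetition time in seconds per volume.
#' @seealso [readMaskedSeries()], [zeroVarianceVoxels()]
#' @export
setClass("MaskedSeries",
  representation(subjectID = "character", data = "matrix", tr = "numeric"),
  prototype(tr = 1),
  validity = function(object) {
    msg <- character()
    if (length(object@subjectID) != 1L) msg <- c(msg, "subjectID must be a scalar")
    if (!all(is.finite(object@data))) msg <- c(msg, "series values must be finite")
    if (ncol(object@data) < 10L) msg <- c(msg, "need at least T = 10 timepoints")
    if (length(msg)) msg else TRUE
  })

#' One subject's dense voxel-by-voxel connectome
#'
#' Pearson correlations between all in-mask voxel pairs. Rows/columns of
#' voxels with zero temporal variance are set to 0 and flagged, never dropped.
#'
#' @slot values numeric N x N correlation matrix.
#' @slot subjectID character scalar.
#' @slot zeroVariance logical length-N flag of zero-variance voxels.
#' @seealso [denseConnectome()]
#' @export
setClass("DenseConnectome",
  representation(values = "matrix", subjectID = "character",
                 zeroVariance = "logical"),
  validity = function(object) {
    msg <- character()
    v <- object@values
    if (nrow(v) != ncol(v)) msg <- c(msg, "connectome must be square")
    if (length(object@zeroVariance) != nrow(v))
      msg <- c(msg, "zeroVariance flag must have length N")
    if (any(abs(v) > 1 + 1e-8)) msg <- c(msg, "correlations must lie in [-1, 1]")
    ok <- !object@zeroVariance
    if (nrow(v) && any(abs(diag(v)[ok] - 1) > 1e-8))
      msg <- c(msg, "diagonal must equal 1 at non-degenerate voxels")
    if (length(msg)) msg else TRUE
  })

#' Maturational dense connectome: age-effect t-values on voxel-pair connectivity
#'
#' @slot tValues numeric N x N matrix of t-statistics for the age effect.
#' @slot beta numeric N x N matrix of slopes (change in r per week), or 0 x 0.
#' @slot df integer residual degrees of freedom (K - 2).
#' @slot thresholded logical; TRUE once negatives have been clamped to 0.
#' @slot degenerate logical N x N flag of elements with zero residual variance
#'   (t set to +/-Inf sentinel), or 0 x 0 when none.
#' @seealso [fitAgeEffect()], [thresholdPositive()]
#' @export
setClass("MaturationalDense",
  representation(tValues = "matrix", beta = "matrix", df = "integer",
                 thresholded = "logical", degenerate = "matrix"),
  prototype(beta = matrix(0, 0, 0), thresholded = FALSE,
            degenerate = matrix(FALSE, 0, 0)),
  validity = function(object) {
    msg <- character()
    tv <- object@tValues
    if (nrow(tv) != ncol(tv)) msg <- c(msg, "t matrix must be square")
    if (nrow(tv) && any(diag(tv) != 0))
      msg <- c(msg, "diagonal must be 0 (self-connectivity carries no age information)")
    if (object@thresholded && any(tv < 0, na.rm = TRUE))
      msg <- c(msg, "thresholded matrix must be non-negative")
    if (object@df < 1L) msg <- c(msg, "df must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Reduced basis from incremental block SVD
#'
#' @slot components numeric R x N matrix; rows are singular-value-weighted
#'   right singular vectors of the accumulated matrix.
#' @slot singularValues numeric length-R retained singular values.
#' @slot rankKept integer R.
#' @seealso [incrementalBlockSVD()]
#' @export
setClass("ReducedBasis",
  representation(components = "matrix", singularValues = "numeric",
                 rankKept = "integer"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@components) != object@rankKept)
      msg <- c(msg, "rankKept must equal number of component rows")
    if (length(object@singularValues) != object@rankKept)
      msg <- c(msg, "one singular value per retained component")
    if (length(msg)) msg else TRUE
  })

#' Set of z-scored spatial maps (matnets or group-ICA components)
#'
#' Each map has mean 0 and sd 1 over the mask, non-negative skewness (sign
#' convention), and maps are ordered by explained variance of the input.
#'
#' @slot maps numeric M x N matrix of z-scored spatial maps.
#' @slot mixing numeric R x M (or T x M) mixing matrix.
#' @slot kind character, "matnet" or "group_ica".
#' @slot seed integer ICA seed used.
#' @slot varExplained numeric length-M explained-variance shares.
#' @seealso [spatialIca()], [groupIca()], [thresholdMaps()]
#' @export
setClass("SpatialMapSet",
  representation(maps = "matrix", mixing = "matrix", kind = "character",
                 seed = "integer", varExplained = "numeric"),
  prototype(kind = "matnet", seed = NA_integer_, varExplained = numeric()),
  validity = function(object) {
    msg <- character()
    if (nrow(object@maps) < 1L) msg <- c(msg, "need at least one map")
    if (!object@kind %in% c("matnet", "group_ica", "truth", "display"))
      msg <- c(msg, "unknown map-set kind")
    if (length(msg)) msg else TRUE
  })

#' Emerging connectivity profiles (complementary maps)
#'
#' Row m holds the regression slopes of matnet m against every column of the
#' thresholded maturational dense connectome: the map of targets to which the
#' matnet's connectivity grows with age.
#'
#' @slot slopes numeric M x N matrix of slope coefficients.
#' @seealso [connectivityProfiles()]
#' @export
setClass("ConnectivityProfiles",
  representation(slopes = "matrix"),
  validity = function(object) {
    if (!all(is.finite(object@slopes))) "slopes must be finite" else TRUE
  })

#' Maturational connectome: similarity of emerging connectivity profiles
#'
#' @slot corr numeric M x M Pearson correlation matrix between profile rows.
#' @slot zeroVariance logical length-M flag of zero-variance profiles.
#' @seealso [maturationalConnectome()]
#' @export
setClass("MatnetConnectome",
  representation(corr = "matrix", zeroVariance = "logical"),
  validity = function(object) {
    msg <- character()
    v <- object@corr
    if (nrow(v) != ncol(v)) msg <- c(msg, "connectome must be square")
    if (any(abs(v) > 1 + 1e-8)) msg <- c(msg, "entries must lie in [-1, 1]")
    if (max(abs(v - t(v))) > 1e-10) msg <- c(msg, "matrix must be symmetric")
    if (length(msg)) msg else TRUE
  })

#' Spectral embedding coordinates of the maturational connectome
#'
#' @slot coords numeric M x dim matrix; columns are eigenvectors of the
#'   symmetric normalised graph Laplacian for the dim smallest strictly
#'   positive eigenvalues, ascending.
#' @slot eigenvalues numeric retained eigenvalues (in `[0, 2]`).
#' @seealso [laplacianEmbedding()]
#' @export
setClass("EmbeddingCoords",
  representation(coords = "matrix", eigenvalues = "numeric"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@coords) != length(object@eigenvalues))
      msg <- c(msg, "one eigenvalue per coordinate dimension")
    if (any(object@eigenvalues < -1e-8 | object@eigenvalues > 2 + 1e-8))
      msg <- c(msg, "normalised Laplacian eigenvalues must lie in [0, 2]")
    if (length(msg)) msg else TRUE
  })

#' Grouping of networks by hierarchical clustering of embedding coordinates
#'
#' @slot labels integer group id per network.
#' @slot nGroups integer number of groups G.
#' @slot linkage the full `hclust` object, retained for the dendrogram.
#' @seealso [wardPartition()]
#' @export
setClass("GroupPartition",
  representation(labels = "integer", nGroups = "integer", linkage = "ANY"),
  validity = function(object) {
    msg <- character()
    if (length(unique(object@labels)) != object@nGroups)
      msg <- c(msg, "nGroups must equal number of distinct labels")
    sizes <- table(object@labels)
    if (object@nGroups > 1L && any(sizes < 2L))
      msg <- c(msg, "no group may be a singleton unless G = 1")
    if (length(msg)) msg else TRUE
  })

#' Maturational hub maps, one per network group
#'
#' The first principal component across a group's complementary maps: the
#' group's shared target territory for emerging connections.
#'
#' @slot maps numeric G x N matrix of hub maps.
#' @slot varExplained numeric length-G explained-variance share of PC1.
#' @slot members list of integer vectors: matnet indices per group.
#' @slot flagged integer indices of single-map groups (hub = the map itself).
#' @seealso [hubMaps()]
#' @export
setClass("HubMaps",
  representation(maps = "matrix", varExplained = "numeric", members = "list",
                 flagged = "integer"),
  prototype(flagged = integer()),
  validity = function(object) {
    if (nrow(object@maps) != length(object@members))
      "one hub map per group" else TRUE
  })

#' Matnet-complementary-map coupling trajectory across the cohort
#'
#' @slot table data.frame with columns subject, age, coupling (Pearson r per
#'   subject between the two z-weighted average timecourses).
#' @slot order integer selected polynomial order (BIC over the search set).
#' @slot coefficients numeric fitted polynomial coefficients (raw basis).
#' @slot fit the selected `lm` fit.
#' @slot alpha numeric confidence level for the band.
#' @slot band data.frame with age grid, fitted values and confidence limits.
#' @seealso [couplingTrajectory()]
#' @export
setClass("CouplingTrajectory",
  representation(table = "data.frame", order = "integer",
                 coefficients = "numeric", fit = "ANY", alpha = "numeric",
                 band = "data.frame"),
  validity = function(object) {
    if (any(abs(object@table$coupling) > 1 + 1e-8))
      "per-subject couplings must lie in [-1, 1]" else TRUE
  })

#' Per-subject network estimates from dual regression
#'
#' @slot timecourses numeric T x M stage-1 timecourses (variance-normalised
#'   before stage 2).
#' @slot maps numeric M x N stage-2 subject maps.
#' @slot subjectID character scalar.
#' @seealso [dualRegression()]
#' @export
setClass("SubjectNetworkEstimates",
  representation(timecourses = "matrix", maps = "matrix",
                 subjectID = "character"))

#' Mass-univariate age-effect t-maps for dual-regression subject maps
#'
#' @slot tMaps numeric M x N matrix of age-effect t-values.
#' @slot df integer K - 2.
#' @seealso [massUnivariateAge()]
#' @export
setClass("AgeEffectMaps",
  representation(tMaps = "matrix", df = "integer"),
  validity = function(object) {
    if (object@df < 1L) "df must be >= 1" else TRUE
  })

#' Seed-to-brain map pair: group mean and age effect
#'
#' @slot groupMean numeric N-length map of subject-averaged seed correlations.
#' @slot ageT numeric N-length map of age-effect t-values.
#' @slot seedVoxels integer indices of the seed voxels.
#' @slot excluded character ids of subjects excluded (all-zero seed timecourse).
#' @seealso [seedToBrain()]
#' @export
setClass("SeedMapPair",
  representation(groupMean = "numeric", ageT = "numeric",
                 seedVoxels = "integer", excluded = "character"),
  prototype(excluded = character()))

#' Spatial parcellation of the mask
#'
#' @slot labels integer parcel label (1..P) per in-mask voxel.
#' @slot centres numeric P x 3 centre-of-gravity per parcel, mm coordinates.
#' @seealso [distanceSimilarity()]
#' @export
setClass("Parcellation",
  representation(labels = "integer", centres = "matrix"),
  validity = function(object) {
    msg <- character()
    p <- nrow(object@centres)
    if (!all(object@labels %in% seq_len(p)))
      msg <- c(msg, "labels must lie in 1..P")
    if (!all(seq_len(p) %in% object@labels))
      msg <- c(msg, "every parcel must be nonempty")
    if (length(msg)) msg else TRUE
  })

#' Global framewise-displacement motion model
#'
#' @slot summary numeric K x (params * stacks) matrix of mean absolute
#'   framewise displacements, standardised column-wise across subjects.
#' @slot scores numeric length-K PC1 scores, sign-aligned to row-mean motion.
#' @slot loadings numeric PC1 loadings over retained columns.
#' @slot dropped integer indices of zero-variance columns removed before PCA.
#' @seealso [fdGlobal()]
#' @export
setClass("FDModel",
  representation(summary = "matrix", scores = "numeric", loadings = "numeric",
                 dropped = "integer"),
  prototype(dropped = integer()))

#' Ground-truth specification for the synthetic cohort generator
#'
#' @slot networkMaps numeric P x N non-negative ground-truth spatial maps.
#' @slot baselineCoupling numeric P x P symmetric age-independent latent
#'   correlation matrix (unit diagonal).
#' @slot couplingSlope numeric P x P symmetric per-week increments, nonzero
#'   only on declared emerging edges.
#' @slot ageRef numeric age (weeks) at which the latent covariance equals the
#'   baseline.
#' @slot noiseSd numeric marginal sd of the additive voxel noise.
#' @slot smearFwhm numeric length-2 c(young, old): spatial FWHM (mm) of the
#'   noise smearing kernel at the youngest and oldest age of the design range;
#'   interpolated linearly in age (monotone non-increasing).
#' @slot smearAgeRange numeric length-2 ages (weeks) at which smearFwhm is
#'   anchored.
#' @slot smearSignal logical; if TRUE the network maps themselves are smeared
#'   per subject (peak-preserving), emulating common-space blurring of the
#'   signal, not only of the noise.
#' @slot motionTargetR numeric target correlation between age and the latent
#'   motion factor, or NA for no motion simulation.
#' @slot mask the [GridMask-class] the maps live on.
#' @seealso [truthSpec()], [generateCohort()]
#' @export
setClass("TruthSpec",
  representation(networkMaps = "matrix", baselineCoupling = "matrix",
                 couplingSlope = "matrix", ageRef = "numeric",
                 noiseSd = "numeric", smearFwhm = "numeric",
                 smearAgeRange = "numeric", smearSignal = "logical",
                 motionTargetR = "numeric", mask = "GridMask"),
  validity = function(object) {
    msg <- character()
    p <- nrow(object@networkMaps)
    if (any(object@networkMaps < 0)) msg <- c(msg, "network maps must be non-negative")
    if (!identical(dim(object@baselineCoupling), c(p, p)) ||
        !identical(dim(object@couplingSlope), c(p, p)))
      msg <- c(msg, "coupling matrices must be P x P")
    else {
      if (max(abs(object@baselineCoupling - t(object@baselineCoupling))) > 1e-10 ||
          max(abs(object@couplingSlope - t(object@couplingSlope))) > 1e-10)
        msg <- c(msg, "coupling matrices must be symmetric")
      if (any(diag(object@couplingSlope) != 0))
        msg <- c(msg, "coupling slopes act on edges, not variances")
    }
    if (ncol(object@networkMaps) != nrow(object@mask@coords))
      msg <- c(msg, "maps must match the mask")
    if (length(object@smearFwhm) != 2L || diff(object@smearFwhm) > 0)
      msg <- c(msg, "smearFwhm must be c(young, old) with young >= old")
    if (length(msg)) msg else TRUE
  })
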