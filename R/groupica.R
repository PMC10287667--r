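#' @include AllClasses.R migp.R ica.R
NULL

#' Group ICA over temporally concatenated subjects
#'
#' The reference pipeline's group factorisation: per-subject voxelwise
#' variance normalisation (optional), temporal concatenation streamed through
#' the incremental block SVD with subjects as blocks, then spatial ICA.
#'
#' @param seriesList list of >= 2 [MaskedSeries-class] on a common mask.
#' @param mComponents number of group components M.
#' @param rKeep reduction rank of the incremental SVD.
#' @param seed ICA seed.
#' @param varNorm variance-normalise each voxel's timecourse per subject
#'   before concatenation (default TRUE).
#' @param ... further arguments to [spatialIca()].
#' @return a [SpatialMapSet-class] of kind "group_ica".
#' @export
groupIca <- function(seriesList, mComponents, rKeep, seed = 1L,
                     varNorm = TRUE, ...) {
  if (length(seriesList) < 2L) stop("need at least 2 subjects")
  getBlock <- function(i) {
    x <- seriesList[[i]]@data
    x <- x - rowMeans(x)
    if (varNorm) {
      s <- sqrt(rowMeans(x^2))
      s[s < 1e-12] <- 1
      x <- x / s
    }
    x                                   # N x T_i column block
  }
  red <- incrementalBlockSVD(getBlock, nBlocks = length(seriesList),
                             rKeep = rKeep)
  spatialIca(red, mComponents, seed = seed, kind = "group_ica", ...)
}

#' Dual regression of group maps against one subject's data
#'
#' Stage 1 regresses each timepoint's voxel pattern on the demeaned group
#' maps, giving T x M subject timecourses. Stage 2 regresses each voxel's
#' timecourse on the (variance-normalised) stage-1 timecourses, giving the
#' M x N subject-specific maps.
#'
#' @param groupMaps a [SpatialMapSet-class] (or bare M x N matrix).
#' @param series a [MaskedSeries-class] on the same mask.
#' @param varNormTimecourses variance-normalise stage-1 timecourses before
#'   stage 2 (the common dual-regression variant; default TRUE).
#' @return a [SubjectNetworkEstimates-class].
#' @export
dualRegression <- function(groupMaps, series, varNormTimecourses = TRUE) {
  g <- if (is(groupMaps, "SpatialMapSet")) groupMaps@maps else groupMaps
  y <- series@data                       # N x T
  if (ncol(g) != nrow(y))
    stop("alignment error: group maps and series disagree on N")
  x1 <- t(g - rowMeans(g))               # N x M demeaned spatial design
  qx <- qr(x1)
  if (qx$rank < ncol(x1)) {
    dep <- setdiff(seq_len(ncol(x1)), qx$pivot[seq_len(qx$rank)])
    stop("rank error: collinear group map(s): ",
         paste(dep, collapse = ", "))
  }
  tc <- qr.coef(qx, y)                   # M x T
  tc <- t(tc)                            # T x M stage-1 timecourses
  tc2 <- tc
  if (varNormTimecourses) {
    s <- apply(tc2, 2, stats::sd)
    if (any(s < 1e-12)) stop("rank error: degenerate stage-1 timecourse")
    tc2 <- sweep(tc2, 2, s, "/")
  }
  qt2 <- qr(cbind(1, tc2))
  sm <- qr.coef(qt2, t(y))[-1, , drop = FALSE]   # M x N subject maps
  new("SubjectNetworkEstimates", timecourses = tc2, maps = sm,
      subjectID = series@subjectID)
}

#' Mass-univariate age modelling of dual-regression subject maps
#'
#' Per component and voxel, OLS of the subject map value on `[1, age]`;
#' returns t-statistics with df = K - 2.
#'
#' @param subjectMaps list of per-subject M x N map matrices (or
#'   [SubjectNetworkEstimates-class]), in cohort order.
#' @param cohort a [CohortTable-class].
#' @return an [AgeEffectMaps-class].
#' @export
massUnivariateAge <- function(subjectMaps, cohort) {
  stopifnot(is(cohort, "CohortTable"))
  k <- length(cohort@age)
  if (length(subjectMaps) != k)
    stop("one subject map set per cohort row required")
  getM <- function(i) {
    m <- subjectMaps[[i]]
    if (is(m, "SubjectNetworkEstimates")) m@maps else m
  }
  a <- cohort@age
  abar <- mean(a)
  sxx <- sum((a - abar)^2)
  s1 <- s2 <- sxy <- NULL
  for (i in seq_len(k)) {
    y <- getM(i)
    if (is.null(s1)) { s1 <- y * 0; s2 <- y * 0; sxy <- y * 0 }
    s1 <- s1 + y; s2 <- s2 + y * y; sxy <- sxy + a[i] * y
  }
  sxyC <- sxy - abar * s1
  syy <- pmax(s2 - s1 * s1 / k, 0)
  beta <- sxyC / sxx
  rss <- pmax(syy - beta * sxyC, 0)
  df <- k - 2L
  se <- sqrt(rss / df / sxx)
  tval <- beta / se
  constant <- syy <= 1e-14 * pmax(s2, k)
  tval[constant] <- 0
  new("AgeEffectMaps", tMaps = tval, df = df)
}

#' Spatial correlation between group maps and their age-effect t-maps
#'
#' The bias diagnostic: for each component, the Pearson correlation over the
#' mask between the group map and the corresponding age-effect t-map. Strong
#' negative correlations indicate that apparent "maturational decline" tracks
#' the component layout itself — the signature of age-dependent effective
#' resolution.
#'
#' @param groupMaps a [SpatialMapSet-class] (or M x N matrix).
#' @param ageMaps an [AgeEffectMaps-class] (or M x N matrix).
#' @return a list with `r` (per-component correlation), `median`, and
#'   `summary` (quartiles).
#' @export
mapAgeEffectBias <- function(groupMaps, ageMaps) {
  g <- if (is(groupMaps, "SpatialMapSet")) groupMaps@maps else groupMaps
  t_ <- if (is(ageMaps, "AgeEffectMaps")) ageMaps@tMaps else ageMaps
  stopifnot(identical(dim(g), dim(t_)))
  r <- vapply(seq_len(nrow(g)),
              function(i) stats::cor(g[i, ], t_[i, ]), numeric(1))
  list(r = r, median = stats::median(r),
       summary = stats::quantile(r, c(0.25, 0.5, 0.75)))
}

#' Benjamini-Hochberg FDR correction for age-effect t-maps
#'
#' Optional utility; the pipeline itself reports unthresholded t-maps.
#'
#' @param ageMaps an [AgeEffectMaps-class].
#' @return matrix of BH-adjusted two-sided p-values, same shape as the t-maps.
#' @export
ageEffectFdr <- function(ageMaps) {
  p <- 2 * stats::pt(abs(ageMaps@tMaps), df = ageMaps@df, lower.tail = FALSE)
  matrix(stats::p.adjust(p, method = "BH"), nrow(p), ncol(p))
}
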