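#' @include AllClasses.R accessors.R
NULL

# per-element OLS t of y (K x N matrix) on [1, age]
ageTColumns <- function(y, age) {
  k <- length(age)
  abar <- mean(age)
  sxx <- sum((age - abar)^2)
  s1 <- colSums(y)
  s2 <- colSums(y^2)
  sxy <- colSums(y * age)
  sxyC <- sxy - abar * s1
  syy <- pmax(s2 - s1^2 / k, 0)
  beta <- sxyC / sxx
  rss <- pmax(syy - beta * sxyC, 0)
  se <- sqrt(rss / (k - 2) / sxx)
  tval <- beta / se
  tval[syy <= 1e-14 * pmax(s2, k)] <- 0
  tval
}

#' Seed-to-brain maps: group mean and age effect
#'
#' Per subject, the seed's mean timecourse is correlated with every voxel;
#' the group-mean map is the simple average of these maps across subjects
#' (raw r by default) and the age-effect map is the per-voxel OLS t-statistic
#' on `[1, age]`. Subjects whose seed timecourse is all zero are excluded
#' with a warning.
#'
#' @param seriesList list of [MaskedSeries-class], in cohort order.
#' @param cohort a [CohortTable-class].
#' @param seedVoxels integer indices (mask order) of the seed voxels (>= 1).
#' @param fisherAverage average Fisher-z-transformed correlations instead of
#'   raw r (default FALSE).
#' @return a [SeedMapPair-class].
#' @export
seedToBrain <- function(seriesList, cohort, seedVoxels,
                        fisherAverage = FALSE) {
  stopifnot(length(seedVoxels) >= 1L,
            length(seriesList) == length(cohort@age))
  k <- length(seriesList)
  n <- nrow(seriesList[[1]]@data)
  subjMaps <- matrix(NA_real_, k, n)
  keep <- logical(k)
  for (i in seq_len(k)) {
    x <- seriesList[[i]]@data
    seedTc <- colMeans(x[seedVoxels, , drop = FALSE])
    if (stats::sd(seedTc) < 1e-12) next
    r <- as.numeric(stats::cor(seedTc, t(x)))
    r[is.na(r)] <- 0                     # zero-variance voxels
    subjMaps[i, ] <- r
    keep[i] <- TRUE
  }
  if (!any(keep)) stop("seed timecourse degenerate in every subject")
  if (!all(keep))
    warning("excluded ", sum(!keep),
            " subject(s) with all-zero seed timecourse")
  sm <- subjMaps[keep, , drop = FALSE]
  groupMean <- if (fisherAverage)
    tanh(colMeans(atanh(pmin(pmax(sm, -1 + 1e-12), 1 - 1e-12))))
  else colMeans(sm)
  ageT <- ageTColumns(sm, cohort@age[keep])
  new("SeedMapPair", groupMean = groupMean, ageT = ageT,
      seedVoxels = as.integer(seedVoxels),
      excluded = cohort@subjectID[!keep])
}

#' Homologous interhemispheric connectivity map
#'
#' Per voxel, the Pearson correlation between its timecourse and its mirror
#' partner's. Voxels without a partner (e.g., midline) are NA. The map is
#' mirror-symmetric by construction.
#'
#' @param series a [MaskedSeries-class].
#' @param mask a [GridMask-class] with mirror pairing
#'   (see [computeMirrorPairs()]).
#' @return numeric N-length map, NA where no partner exists.
#' @export
homologousConnectivity <- function(series, mask) {
  mp <- mask@mirrorPair
  if (!length(mp)) stop("mask carries no mirror pairing")
  x <- series@data
  out <- rep(NA_real_, nrow(x))
  ok <- which(!is.na(mp))
  xc <- x - rowMeans(x)
  ss <- sqrt(rowSums(xc^2))
  num <- rowSums(xc[ok, , drop = FALSE] * xc[mp[ok], , drop = FALSE])
  den <- ss[ok] * ss[mp[ok]]
  out[ok] <- ifelse(den < 1e-24, 0, num / den)
  out
}

#' Cohort-level age effect on homologous connectivity
#'
#' @param seriesList list of [MaskedSeries-class], in cohort order.
#' @param cohort a [CohortTable-class].
#' @param mask a mirror-paired [GridMask-class].
#' @return list with `maps` (K x N per-subject homologous maps) and `ageT`
#'   (N-length t map, NA where undefined).
#' @export
homologousAgeEffect <- function(seriesList, cohort, mask) {
  hm <- t(vapply(seriesList, homologousConnectivity,
                 numeric(nVoxels(mask)), mask = mask))
  ok <- !colAnyNA(hm)
  ageT <- rep(NA_real_, ncol(hm))
  ageT[ok] <- ageTColumns(hm[, ok, drop = FALSE], cohort@age)
  list(maps = hm, ageT = ageT)
}

colAnyNA <- function(m) colSums(is.na(m)) > 0

#' Extract suprathreshold seed clusters from an age-effect map
#'
#' Thresholds the map (positively at `zPos`, or negatively at `zNeg` for
#' white-matter-style seeds), labels 26-connected components on the lattice,
#' and reports cluster sizes. An empty suprathreshold set returns an empty
#' result, not an error.
#'
#' @param ageMap numeric N-length map (mask order); NA treated as
#'   subthreshold.
#' @param mask a [GridMask-class].
#' @param zPos positive threshold (used when `negative = FALSE`).
#' @param zNeg negative threshold (used when `negative = TRUE`).
#' @param negative threshold negatively instead (default FALSE).
#' @return list with `labels` (integer N-length, 0 = subthreshold, clusters
#'   numbered by decreasing size) and `sizes` (integer vector).
#' @export
seedsFromAgeMap <- function(ageMap, mask, zPos = 3, zNeg = -3,
                            negative = FALSE) {
  stopifnot(length(ageMap) == nVoxels(mask))
  above <- if (negative) !is.na(ageMap) & ageMap < zNeg
           else !is.na(ageMap) & ageMap > zPos
  labels <- integer(length(ageMap))
  if (!any(above))
    return(list(labels = labels, sizes = integer()))
  co <- mask@coords[above, , drop = FALSE]
  idx <- which(above)
  # lattice hash -> position among suprathreshold voxels
  key <- function(m) (m[, 1] * 1e6 + m[, 2] * 1e3 + m[, 3])
  keyVec <- key(co)
  comp <- integer(nrow(co))
  cur <- 0L
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, ]
  for (i in seq_len(nrow(co))) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      queue <- i
      comp[i] <- cur
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        nbKeys <- key(sweep(offsets, 2, co[v, ], "+"))
        nb <- match(nbKeys, keyVec)
        nb <- nb[!is.na(nb)]
        nb <- nb[comp[nb] == 0L]
        comp[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  sizes <- as.integer(table(comp))
  ord <- order(sizes, decreasing = TRUE)
  relabel <- integer(length(sizes))
  relabel[ord] <- seq_along(ord)
  labels[idx] <- relabel[comp]
  list(labels = labels, sizes = sort(sizes, decreasing = TRUE))
}

#' Parcellate the mask by k-means on voxel coordinates
#'
#' @param mask a [GridMask-class].
#' @param P number of parcels (<= N).
#' @param seed RNG seed for the k-means initialisation.
#' @param maxRestarts re-runs allowed if a parcel comes back empty.
#' @return a [Parcellation-class] with per-parcel mm centres of gravity.
#' @export
parcellateMask <- function(mask, P = 300L, seed = 1L, maxRestarts = 5L) {
  xyz <- mmCoords(mask)
  if (P > nrow(xyz)) stop("more parcels than voxels")
  oldSeed <- globalSeed()
  on.exit(restoreSeed(oldSeed), add = TRUE)
  for (att in seq_len(maxRestarts)) {
    set.seed(as.integer(seed) + att - 1L)
    km <- try(suppressWarnings(stats::kmeans(xyz, centers = P,
                                             iter.max = 500L, nstart = 3L)),
              silent = TRUE)
    if (!inherits(km, "try-error") && all(tabulate(km$cluster, P) > 0))
      break
    km <- NULL
  }
  if (is.null(km)) stop("k-means failed to produce ", P, " nonempty parcels")
  centres <- matrix(0, P, 3)
  for (p in seq_len(P))
    centres[p, ] <- colMeans(xyz[km$cluster == p, , drop = FALSE])
  new("Parcellation", labels = as.integer(km$cluster), centres = centres)
}

#' Distance versus seed-map similarity over a parcellation
#'
#' Parcellates the mask by k-means on voxel mm-coordinates, computes each
#' parcel's seed-to-brain group-mean and age-effect maps, and for every
#' unordered parcel pair records the Euclidean distance between the parcels'
#' centres of gravity and the spatial Pearson correlations between their two
#' kinds of maps. Pair count is P(P-1)/2.
#'
#' @param seriesList list of [MaskedSeries-class], in cohort order.
#' @param cohort a [CohortTable-class].
#' @param mask a [GridMask-class].
#' @param P number of parcels (default 300).
#' @param seed k-means seed.
#' @return list with `pairs` (data.frame: i, j, distance_mm, rGroupMean,
#'   rAgeT), `corGroupMean` and `corAgeT` (the two summary correlations of
#'   distance vs similarity), and the `parcellation`.
#' @export
distanceSimilarity <- function(seriesList, cohort, mask, P = 300L,
                               seed = 1L) {
  parc <- parcellateMask(mask, P = P, seed = seed)
  k <- length(seriesList)
  n <- nVoxels(mask)
  onehot <- matrix(0, P, n)
  onehot[cbind(parc@labels, seq_len(n))] <- 1
  onehot <- onehot / rowSums(onehot)
  meanMaps <- matrix(0, P, n)
  sum1 <- matrix(0, P, n); sum2 <- matrix(0, P, n); sumxy <- matrix(0, P, n)
  age <- cohort@age
  for (i in seq_len(k)) {
    x <- seriesList[[i]]@data
    parcTc <- onehot %*% x                       # P x T parcel mean tcs
    r <- stats::cor(t(parcTc), t(x))             # P x N seed-to-brain maps
    r[is.na(r)] <- 0
    sum1 <- sum1 + r; sum2 <- sum2 + r^2; sumxy <- sumxy + age[i] * r
  }
  groupMean <- sum1 / k
  abar <- mean(age); sxx <- sum((age - abar)^2)
  sxyC <- sumxy - abar * sum1
  syy <- pmax(sum2 - sum1^2 / k, 0)
  beta <- sxyC / sxx
  rss <- pmax(syy - beta * sxyC, 0)
  tmap <- beta / sqrt(rss / (k - 2) / sxx)
  tmap[syy <= 1e-14 * pmax(sum2, k)] <- 0
  d <- as.matrix(stats::dist(parc@centres))
  rMean <- stats::cor(t(groupMean))
  rAge <- stats::cor(t(tmap))
  ut <- upper.tri(d)
  pairs <- data.frame(i = row(d)[ut], j = col(d)[ut], distance_mm = d[ut],
                      rGroupMean = rMean[ut], rAgeT = rAge[ut])
  list(pairs = pairs,
       corGroupMean = stats::cor(pairs$distance_mm, pairs$rGroupMean),
       corAgeT = stats::cor(pairs$distance_mm, pairs$rAgeT),
       parcellation = parc)
}

#' Global motion model from framewise displacement summaries
#'
#' Per subject and per (motion parameter, stack), the mean absolute
#' frame-to-frame displacement is computed from the motion traces; the
#' K x (params * stacks) summary matrix is standardised column-wise across
#' subjects and its first principal component is the global between-subject
#' motion measure. Zero-variance columns are dropped with a warning; the PC1
#' sign is aligned to positive correlation with row-mean motion.
#'
#' @param cohort a [CohortTable-class] whose `motion` slot holds per-subject
#'   (params x stacks x timepoints) traces.
#' @param nParams,nStacks expected trace dimensions (defaults 6 and 16).
#' @return an [FDModel-class].
#' @export
fdGlobal <- function(cohort, nParams = 6L, nStacks = 16L) {
  ids <- cohort@subjectID
  k <- length(ids)
  if (k < 3L) stop("need K >= 3 subjects")
  if (!length(cohort@motion)) stop("cohort carries no motion traces")
  summary <- matrix(NA_real_, k, nParams * nStacks)
  for (i in seq_len(k)) {
    tr <- cohort@motion[[ids[i]]]
    if (is.null(tr)) stop("missing motion trace for subject ", ids[i])
    if (!identical(dim(tr)[1:2], c(as.integer(nParams), as.integer(nStacks))))
      stop("motion trace for ", ids[i], " has shape ",
           paste(dim(tr), collapse = "x"), "; expected ",
           nParams, "x", nStacks, "xT")
    fd <- apply(tr, c(1, 2), function(v) mean(abs(diff(v))))
    summary[i, ] <- as.numeric(fd)
  }
  mu <- colMeans(summary)
  sdc <- apply(summary, 2, stats::sd)
  dropped <- which(sdc < 1e-12)
  if (length(dropped) == ncol(summary))
    stop("all summary columns have zero variance across subjects")
  if (length(dropped))
    warning("dropping ", length(dropped), " zero-variance column(s) before PCA")
  keep <- setdiff(seq_len(ncol(summary)), dropped)
  z <- sweep(sweep(summary[, keep, drop = FALSE], 2, mu[keep]), 2,
             sdc[keep], "/")
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  scores <- pc$x[, 1]
  if (stats::cor(scores, rowMeans(z)) < 0) {
    scores <- -scores
    pc$rotation[, 1] <- -pc$rotation[, 1]
  }
  zfull <- matrix(0, k, ncol(summary))
  zfull[, keep] <- z
  new("FDModel", summary = zfull, scores = as.numeric(scores),
      loadings = as.numeric(pc$rotation[, 1]),
      dropped = as.integer(dropped))
}
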