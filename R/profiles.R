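#' @include AllClasses.R accessors.R
NULL

#' Emerging connectivity profiles (complementary maps)
#'
#' Regresses the matnet maps against every column of the thresholded
#' maturational dense connectome: for column v, a multiple regression of that
#' column on the M demeaned matnet maps (plus intercept). The slopes form
#' column v of the M x N output; row m is matnet m's complementary map — the
#' territory towards which its connectivity grows with age.
#'
#' @param matnets a [SpatialMapSet-class] of matnet maps.
#' @param mdense a thresholded [MaturationalDense-class] on the same mask.
#' @return a [ConnectivityProfiles-class].
#' @export
connectivityProfiles <- function(matnets, mdense) {
  stopifnot(is(mdense, "MaturationalDense"))
  if (!mdense@thresholded)
    stop("profiles are computed against the thresholded maturational dense connectome")
  g <- matnets@maps
  if (ncol(g) != ncol(mdense@tValues))
    stop("alignment error: matnet maps and connectome disagree on N")
  x <- cbind(1, t(g - rowMeans(g)))            # N x (1 + M)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    dep <- setdiff(seq_len(nrow(g)), qx$pivot[seq_len(qx$rank)] - 1L)
    stop("rank error: collinear matnet map(s): ", paste(dep, collapse = ", "))
  }
  slopes <- qr.coef(qx, mdense@tValues)[-1, , drop = FALSE]
  new("ConnectivityProfiles", slopes = slopes)
}

#' Maturational connectome from connectivity profiles
#'
#' Pearson correlation between every pair of profile rows; the M x M result
#' summarises the similarity of the matnets' emerging connectivity profiles.
#' Zero-variance rows get zero correlations and are flagged.
#'
#' @param profiles a [ConnectivityProfiles-class] (M >= 2 rows).
#' @return a [MatnetConnectome-class].
#' @export
maturationalConnectome <- function(profiles) {
  s <- profiles@slopes
  if (nrow(s) < 2L) stop("need at least two profiles")
  sdr <- apply(s, 1, stats::sd)
  zv <- sdr < 1e-12
  cc <- matrix(0, nrow(s), nrow(s))
  if (any(!zv)) {
    r <- stats::cor(t(s[!zv, , drop = FALSE]))
    cc[!zv, !zv] <- (r + t(r)) / 2
  }
  diag(cc) <- 1
  if (any(zv)) warning(sum(zv), " zero-variance profile(s); correlations set to 0")
  new("MatnetConnectome", corr = cc, zeroVariance = zv)
}

#' Spectral embedding of the maturational connectome
#'
#' Builds an affinity graph from the positive off-diagonal correlations,
#' forms the symmetric normalised Laplacian L = I - D^(-1/2) W D^(-1/2), and
#' returns the eigenvectors of the `dim` smallest strictly positive
#' eigenvalues (ascending) as coordinates. Distance in the embedding reads as
#' maturational dissimilarity.
#'
#' @param connectome a [MatnetConnectome-class] (M > dim networks).
#' @param dim embedding dimension (default 3).
#' @param affinity "positive" (default; W = max(r, 0) off-diagonal) or
#'   "shifted" (W = (1 + r) / 2).
#' @param scaleByEigenvalues divide each coordinate by sqrt(eigenvalue)
#'   (default FALSE: plain eigenvectors).
#' @return an [EmbeddingCoords-class].
#' @export
laplacianEmbedding <- function(connectome, dim = 3L,
                               affinity = c("positive", "shifted"),
                               scaleByEigenvalues = FALSE) {
  affinity <- match.arg(affinity)
  r <- connectome@corr
  m <- nrow(r)
  if (m <= dim) stop("need more networks than embedding dimensions")
  w <- switch(affinity, positive = pmax(r, 0), shifted = (1 + r) / 2)
  diag(w) <- 0
  deg <- rowSums(w)
  if (any(deg <= 1e-12))
    stop("isolated node(s) in the affinity graph: ",
         paste(which(deg <= 1e-12), collapse = ", "))
  comp <- graphComponents(w > 0)
  if (max(comp) > 1L)
    stop("affinity graph is disconnected (", max(comp), " components): ",
         paste(tapply(seq_len(m), comp, paste, collapse = "+"),
               collapse = " | "))
  dh <- 1 / sqrt(deg)
  lap <- diag(m) - (dh * w) * rep(dh, each = m)   # D^-1/2 W D^-1/2
  lap <- (lap + t(lap)) / 2
  e <- eigen(lap, symmetric = TRUE)
  ev <- rev(e$values)                              # ascending
  vec <- e$vectors[, rev(seq_len(m)), drop = FALSE]
  pos <- which(ev > 1e-10)
  if (length(pos) < dim) stop("fewer than dim strictly positive eigenvalues")
  sel <- pos[seq_len(dim)]
  coords <- vec[, sel, drop = FALSE]
  if (scaleByEigenvalues) coords <- sweep(coords, 2, sqrt(ev[sel]), "/")
  new("EmbeddingCoords", coords = coords,
      eigenvalues = pmin(pmax(ev[sel], 0), 2))
}

# connected components of an undirected adjacency (logical matrix)
graphComponents <- function(adj) {
  m <- nrow(adj)
  comp <- integer(m)
  cur <- 0L
  for (i in seq_len(m)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      queue <- i
      comp[i] <- cur
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        nb <- which(adj[v, ] & comp == 0L)
        comp[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  comp
}

#' Ward grouping of networks in the embedding space
#'
#' Ward linkage on Euclidean distances between embedding coordinates. The
#' number of groups G is the largest cut count in 2..M whose clusters all
#' have at least 2 members (the finest partitioning with no single-network
#' group); if none qualifies, G = 1. The full linkage is retained for the
#' dendrogram.
#'
#' @param coords an [EmbeddingCoords-class] (or bare M x d matrix), M >= 2.
#' @return a [GroupPartition-class].
#' @export
wardPartition <- function(coords) {
  x <- if (is(coords, "EmbeddingCoords")) coords@coords else coords
  m <- nrow(x)
  if (m < 2L) stop("need at least two networks")
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  g <- 1L
  labels <- rep(1L, m)
  for (k in seq(2L, m)) {
    lab <- stats::cutree(hc, k = k)
    if (min(table(lab)) >= 2L) { g <- k; labels <- lab }
  }
  new("GroupPartition", labels = as.integer(labels), nGroups = g,
      linkage = hc)
}

#' Maturational hub maps, one per network group
#'
#' Within each group, the complementary maps are stacked as observations
#' (rows), centred across maps, and the first right singular vector is taken
#' as the hub map — the group's shared target territory for emerging
#' connections. The sign is aligned to the group-mean map and the explained
#' variance share of the first component is reported. Single-map groups
#' (possible only under manual partitions) return the map itself, flagged.
#'
#' @param profiles a [ConnectivityProfiles-class].
#' @param partition a [GroupPartition-class] over the profile rows.
#' @return a [HubMaps-class].
#' @export
hubMaps <- function(profiles, partition) {
  s <- profiles@slopes
  lab <- partition@labels
  if (length(lab) != nrow(s))
    stop("partition labels must cover every profile row")
  gs <- sort(unique(lab))
  hub <- matrix(0, length(gs), ncol(s))
  ve <- numeric(length(gs))
  members <- vector("list", length(gs))
  flagged <- integer()
  for (j in seq_along(gs)) {
    idx <- which(lab == gs[j])
    members[[j]] <- idx
    grp <- s[idx, , drop = FALSE]
    meanMap <- colMeans(grp)
    if (length(idx) == 1L) {
      hub[j, ] <- grp[1, ]
      ve[j] <- 1
      flagged <- c(flagged, j)
      next
    }
    cen <- grp - rowMeans(grp)
    sv <- svd(cen, nu = 0, nv = 1)
    h <- sv$v[, 1]
    if (sum(h * meanMap) < 0) h <- -h
    hub[j, ] <- h
    ve[j] <- sv$d[1]^2 / sum(sv$d^2)
  }
  if (length(flagged))
    warning("single-map group(s): ", paste(flagged, collapse = ", "),
            "; hub set to the map itself")
  new("HubMaps", maps = hub, varExplained = ve, members = members,
      flagged = flagged)
}

#' Matnet-complementary-map coupling trajectory across the cohort
#'
#' Both maps are thresholded at `z > zThresh` to reduce spatial overlap; per
#' subject, each map's timecourse is the z-weighted average of its
#' suprathreshold voxels and the coupling is their Pearson correlation. A
#' polynomial in age is fitted to the couplings, its order chosen by BIC over
#' the search set, with a confidence band at level `1 - alpha`.
#'
#' @param matnetMap numeric N-length z-valued matnet map.
#' @param complementaryMap numeric N-length z-valued complementary map
#'   (standardise slope maps before thresholding, e.g. with `scale()`).
#' @param seriesList list of [MaskedSeries-class], in cohort order.
#' @param cohort a [CohortTable-class].
#' @param zThresh suprathreshold level (default 5).
#' @param orders polynomial orders searched (default 1:3).
#' @param alpha confidence level complement for the band (default 0.05).
#' @return a [CouplingTrajectory-class].
#' @export
couplingTrajectory <- function(matnetMap, complementaryMap, seriesList,
                               cohort, zThresh = 5, orders = 1:3,
                               alpha = 0.05) {
  zA <- as.numeric(matnetMap)
  zB <- as.numeric(complementaryMap)
  selA <- which(zA > zThresh)
  selB <- which(zB > zThresh)
  if (!length(selA) || !length(selB))
    stop("threshold error: no voxels above z = ", zThresh,
         " in one of the maps; lower zThresh")
  k <- length(cohort@age)
  stopifnot(length(seriesList) == k)
  coupling <- vapply(seq_len(k), function(i) {
    x <- seriesList[[i]]@data
    tcA <- crossprod(x[selA, , drop = FALSE], zA[selA]) / sum(zA[selA])
    tcB <- crossprod(x[selB, , drop = FALSE], zB[selB]) / sum(zB[selB])
    stats::cor(as.numeric(tcA), as.numeric(tcB))
  }, numeric(1))
  tab <- data.frame(subject = cohort@subjectID, age = cohort@age,
                    coupling = coupling)
  fits <- lapply(orders, function(p)
    stats::lm(coupling ~ poly(age, p, raw = TRUE), data = tab))
  bics <- vapply(fits, stats::BIC, numeric(1))
  best <- which.min(bics)
  fit <- fits[[best]]
  grid <- data.frame(age = seq(min(tab$age), max(tab$age), length.out = 100))
  pr <- stats::predict(fit, newdata = grid, interval = "confidence",
                       level = 1 - alpha)
  band <- data.frame(age = grid$age, fit = pr[, "fit"],
                     lower = pr[, "lwr"], upper = pr[, "upr"])
  new("CouplingTrajectory", table = tab, order = as.integer(orders[best]),
      coefficients = stats::coef(fit), fit = fit, alpha = alpha,
      band = band)
}

#' Serialise a linkage tree as a nested-list JSON string
#'
#' @param partition a [GroupPartition-class] carrying an `hclust` linkage.
#' @return a JSON string representing the dendrogram as nested lists with
#'   merge heights.
#' @export
dendrogramJson <- function(partition) {
  hc <- partition@linkage
  build <- function(i) {
    if (i < 0) return(list(leaf = -i))
    list(height = hc$height[i],
         children = list(build(hc$merge[i, 1]), build(hc$merge[i, 2])))
  }
  jsonlite::toJSON(build(nrow(hc$merge)), auto_unbox = TRUE, digits = NA)
}
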