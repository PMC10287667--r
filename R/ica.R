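#' @include AllClasses.R migp.R
NULL

# Symmetric fixed-point ICA with the logcosh contrast on pre-whitened data.
# z: m x N whitened data (unit covariance rows). Returns the unmixing matrix
# or NULL on non-convergence.
fixedPointIca <- function(z, tol, maxit) {
  m <- nrow(z)
  n <- ncol(z)
  w <- matrix(stats::rnorm(m * m), m, m)
  sym <- function(w) {
    e <- eigen(w %*% t(w), symmetric = TRUE)
    solve(e$vectors %*% diag(sqrt(pmax(e$values, 1e-14)), m) %*%
            t(e$vectors)) %*% w
  }
  w <- sym(w)
  for (it in seq_len(maxit)) {
    wz <- w %*% z
    g <- tanh(wz)
    gp <- rowMeans(1 - g^2)
    w1 <- g %*% t(z) / n - diag(gp, m) %*% w
    w1 <- sym(w1)
    delta <- 1 - min(abs(diag(w1 %*% t(w))))
    w <- w1
    if (delta < tol) return(list(w = w, iterations = it))
  }
  NULL
}

#' Spatial ICA factorisation of a reduced basis
#'
#' Whitens the reduced data and runs symmetric fixed-point ICA with the
#' logcosh contrast, treating voxels as samples so the recovered components
#' are spatially independent maps. Output maps are z-scored over the mask,
#' sign-flipped to non-negative skewness, and ordered by the variance of the
#' reduced data they explain.
#'
#' @param reduced a [ReducedBasis-class] (or bare R x N matrix) of
#'   singular-value-weighted components.
#' @param mComponents number of independent components M (<= R).
#' @param seed integer seed controlling the random orthogonal initialisation;
#'   the same input and seed give bitwise-identical maps.
#' @param tol convergence tolerance on the unmixing update (default 1e-6).
#' @param maxit maximum fixed-point iterations per restart (default 1000).
#' @param restarts random re-initialisations before giving up (default 5).
#' @param kind map-set kind label ("matnet" or "group_ica").
#' @return a [SpatialMapSet-class] with M z-scored maps and the R x M mixing
#'   matrix.
#' @export
spatialIca <- function(reduced, mComponents, seed = 1L, tol = 1e-6,
                       maxit = 1000L, restarts = 5L, kind = "matnet") {
  x <- if (is(reduced, "ReducedBasis")) reduced@components else reduced
  r <- nrow(x)
  n <- ncol(x)
  if (mComponents > r)
    stop("mComponents (", mComponents, ") exceeds reduced rank (", r, ")")
  xc <- x - rowMeans(x)
  cov <- xc %*% t(xc) / n
  e <- eigen(cov, symmetric = TRUE)
  keep <- seq_len(mComponents)
  if (any(e$values[keep] <= 1e-12 * e$values[1]))
    stop("reduced data rank below requested mComponents")
  whiten <- diag(1 / sqrt(e$values[keep]), mComponents) %*%
    t(e$vectors[, keep, drop = FALSE])
  z <- whiten %*% xc

  res <- NULL
  oldSeed <- globalSeed()
  on.exit(restoreSeed(oldSeed), add = TRUE)
  for (att in seq_len(restarts)) {
    set.seed(as.integer(seed) + att - 1L)
    res <- fixedPointIca(z, tol, maxit)
    if (!is.null(res)) break
  }
  if (is.null(res))
    stop("spatial ICA failed to converge after ", restarts,
         " restart(s); increase maxit or restarts")

  s <- res$w %*% z                     # M x N independent spatial maps
  a <- xc %*% t(s) / n                 # R x M mixing (rows of s are white)
  ve <- colSums(a^2)
  ord <- order(ve, decreasing = TRUE)
  s <- s[ord, , drop = FALSE]
  a <- a[, ord, drop = FALSE]
  ve <- ve[ord]
  flip <- ifelse(rowSkewness(s) < 0, -1, 1)
  s <- s * flip
  a <- sweep(a, 2, flip, "*")
  s <- zscoreRows(s)
  new("SpatialMapSet", maps = s, mixing = a, kind = kind,
      seed = as.integer(seed), varExplained = ve / sum(e$values))
}

# Save/restore the global RNG state so seeded stages do not perturb the
# caller's stream.
globalSeed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
restoreSeed <- function(s) {
  if (is.null(s)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", s, envir = globalenv())
}

#' Threshold spatial maps for display
#'
#' Sets voxels with `|z| < zAbs` to 0 and reports how many voxels survive in
#' each map.
#'
#' @param mapSet a [SpatialMapSet-class].
#' @param zAbs positive threshold on |z| (`zAbs = 0` leaves maps unchanged).
#' @return a list with `maps` (a thresholded [SpatialMapSet-class], kind
#'   "display") and `nSurviving` (integer per map).
#' @export
thresholdMaps <- function(mapSet, zAbs) {
  stopifnot(is(mapSet, "SpatialMapSet"), zAbs >= 0)
  m <- mapSet@maps
  m[abs(m) < zAbs] <- 0
  list(maps = new("SpatialMapSet", maps = m, mixing = mapSet@mixing,
                  kind = "display", seed = mapSet@seed,
                  varExplained = mapSet@varExplained),
       nSurviving = as.integer(rowSums(m != 0)))
}

#' Derive maturational networks from a thresholded maturational dense connectome
#'
#' Chains [incrementalBlockSVD()] over the thresholded t-matrix (columns as
#' blocks) into [spatialIca()]. `rKeep` is automatically capped at N/4 on
#' small grids so the reduction stays a genuine reduction.
#'
#' @param mdense a thresholded [MaturationalDense-class].
#' @param mComponents number of matnets M (default 25).
#' @param rKeep reduction rank (default 500, capped at N/4).
#' @param nBlocks number of column blocks for the incremental SVD
#'   (default 200, capped so each block has at least one column).
#' @param seed ICA seed.
#' @param ... further arguments to [spatialIca()].
#' @return a [SpatialMapSet-class] of kind "matnet".
#' @export
matnetFactorisation <- function(mdense, mComponents = 25L, rKeep = 500L,
                                nBlocks = 200L, seed = 1L, ...) {
  stopifnot(is(mdense, "MaturationalDense"))
  if (!mdense@thresholded)
    stop("factorise the thresholded maturational dense connectome ",
         "(call thresholdPositive() first)")
  n <- ncol(mdense@tValues)
  rKeep <- max(mComponents, min(rKeep, floor(n / 4)))
  nBlocks <- min(nBlocks, n)
  red <- incrementalBlockSVD(mdense@tValues, nBlocks = nBlocks,
                             rKeep = rKeep)
  spatialIca(red, mComponents, seed = seed, kind = "matnet", ...)
}
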