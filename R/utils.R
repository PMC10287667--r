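# Internal numerical helpers shared across modules.

# FWHM (mm) -> Gaussian sigma in voxel units per axis.
fwhmToSigmaVox <- function(fwhm, voxelSize) {
  (fwhm / (2 * sqrt(2 * log(2)))) / voxelSize
}

# Truncated, per-position renormalised 1D Gaussian convolution matrix (n x n).
# Row renormalisation keeps total mass at volume edges, so smoothing does not
# darken boundaries.
gaussConvMatrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  idx <- seq_len(n)
  d <- outer(idx, idx, "-")
  w <- exp(-d^2 / (2 * sigma^2))
  r <- ceiling(3 * sigma)
  w[abs(d) > r] <- 0
  w / rowSums(w)
}

# Separable Gaussian smoothing of a 3D array, sigma in voxel units (length 3).
smoothVolume <- function(vol, sigmaVox) {
  d <- dim(vol)
  stopifnot(length(d) == 3L)
  k1 <- gaussConvMatrix(d[1], sigmaVox[1])
  k2 <- gaussConvMatrix(d[2], sigmaVox[2])
  k3 <- gaussConvMatrix(d[3], sigmaVox[3])
  x <- matrix(vol, nrow = d[1])              # axis 1 fastest
  x <- k1 %*% x                              # smooth axis 1
  x <- array(x, d)
  x <- aperm(x, c(2, 1, 3))
  x <- array(k2 %*% matrix(x, nrow = d[2]), d[c(2, 1, 3)])
  x <- aperm(x, c(2, 1, 3))
  x <- aperm(x, c(3, 1, 2))
  x <- array(k3 %*% matrix(x, nrow = d[3]), d[c(3, 1, 2)])
  aperm(x, c(2, 3, 1))
}

# z-score rows of a matrix (population sd over columns).
zscoreRows <- function(m, tol = 1e-12) {
  mu <- rowMeans(m)
  s <- sqrt(rowMeans((m - mu)^2))
  s[s < tol] <- 1
  (m - mu) / s
}

rowSkewness <- function(m) {
  mu <- rowMeans(m)
  c2 <- rowMeans((m - mu)^2)
  c3 <- rowMeans((m - mu)^3)
  c3 / pmax(c2, .Machine$double.eps)^1.5
}

#' Largest principal angle between two row spaces
#'
#' Used to compare a reduced basis with a directly computed singular
#' subspace: 0 means identical span.
#'
#' @param a,b matrices whose row spaces are compared.
#' @return the largest principal angle in radians.
#' @export
largestPrincipalAngle <- function(a, b) {
  qa <- qr.Q(qr(t(a)))
  qb <- qr.Q(qr(t(b)))
  s <- svd(crossprod(qa, qb))$d
  acos(max(min(min(s), 1), -1))
}

# Correlation of every row of a against every row of b (rows are maps).
rowCor <- function(a, b) {
  stats::cor(t(a), t(b))
}

# Stable hash-like fingerprint of a numeric object for provenance metadata.
fingerprint <- function(x) {
  v <- as.numeric(x)
  sprintf("%.0f:%.6g:%.6g", length(v), sum(v), sum(v * seq_along(v) %% 97))
}
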