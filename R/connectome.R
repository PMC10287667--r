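#' @include AllClasses.R accessors.R
NULL

#' Per-subject dense voxelwise connectome
#'
#' Pearson correlation between the timecourses of every in-mask voxel pair.
#' Voxels with zero temporal variance get zero rows/columns and are flagged
#' rather than dropped, preserving the mask voxel order.
#'
#' @param series a [MaskedSeries-class] (T >= 10).
#' @return a [DenseConnectome-class].
#' @export
denseConnectome <- function(series) {
  stopifnot(is(series, "MaskedSeries"))
  x <- series@data
  zv <- zeroVarianceVoxels(series)
  v <- matrix(0, nrow(x), nrow(x))
  ok <- !zv
  if (any(ok)) {
    r <- stats::cor(t(x[ok, , drop = FALSE]))
    r <- (r + t(r)) / 2          # symmetrise exactly against rounding
    r[r > 1] <- 1
    r[r < -1] <- -1
    v[ok, ok] <- r
  }
  diag(v)[ok] <- 1
  new("DenseConnectome", values = v, subjectID = series@subjectID,
      zeroVariance = zv)
}

#' Element-wise age regression of dense connectomes across the cohort
#'
#' Each voxel-pair correlation is fitted across subjects by OLS on the
#' two-parameter design `[1, age]`; the slope t-statistic (df = K - 2) fills
#' the maturational dense connectome. Computation streams sufficient
#' statistics (sums of y, y^2 and y*age per element), so only a constant
#' number of N x N accumulators is ever resident regardless of K, and the
#' result is exactly the per-element OLS fit.
#'
#' Elements with zero residual variance (degenerate noiseless input) receive a
#' +/-Inf sentinel and are flagged; the diagonal is set to 0.
#'
#' @param connectomes a list of [DenseConnectome-class] objects in cohort
#'   order, or a function `function(i)` returning subject i's connectome on
#'   demand (streaming; nothing else is retained).
#' @param cohort a [CohortTable-class] (K >= 3, nondegenerate ages).
#' @param fisher apply the Fisher z-transform `atanh(r)` before fitting.
#'   Default FALSE: correlations are regressed as raw r; enabling it changes
#'   the slope's units.
#' @return a [MaturationalDense-class] with t-values, slopes and df = K - 2.
#' @export
fitAgeEffect <- function(connectomes, cohort, fisher = FALSE) {
  stopifnot(is(cohort, "CohortTable"))
  k <- length(cohort@age)
  if (k < 3L) stop("design error: need K >= 3 subjects")
  getC <- if (is.function(connectomes)) connectomes
          else function(i) connectomes[[i]]
  a <- cohort@age
  abar <- mean(a)
  sxx <- sum((a - abar)^2)

  s1 <- s2 <- sxy <- NULL
  n <- 0L
  for (i in seq_len(k)) {
    ci <- getC(i)
    y <- if (is(ci, "DenseConnectome")) ci@values else ci
    if (fisher) {
      y <- atanh(pmin(pmax(y, -1 + 1e-12), 1 - 1e-12))
    }
    if (is.null(s1)) {
      n <- nrow(y)
      s1 <- matrix(0, n, n); s2 <- matrix(0, n, n); sxy <- matrix(0, n, n)
    }
    s1 <- s1 + y
    s2 <- s2 + y * y
    sxy <- sxy + a[i] * y
  }
  sxyC <- sxy - abar * s1                 # centred cross-products
  syy <- pmax(s2 - s1 * s1 / k, 0)
  beta <- sxyC / sxx
  rss <- pmax(syy - beta * sxyC, 0)
  df <- k - 2L
  # constant elements (no variance across subjects): slope and t are 0;
  # perfect noiseless fits (zero residual, nonzero variance): +/-Inf sentinel
  constant <- syy <= 1e-14 * pmax(s2, k)
  degenerate <- !constant & rss <= 1e-12 * syy
  se <- sqrt(rss / df / sxx)
  tval <- beta / se
  tval[constant] <- 0
  beta[constant] <- 0
  tval[degenerate] <- sign(beta[degenerate]) * Inf
  diag(tval) <- 0
  diag(beta) <- 0
  if (any(degenerate))
    warning(sum(degenerate), " element(s) with zero residual variance; ",
            "t set to +/-Inf sentinel and flagged")
  new("MaturationalDense", tValues = tval, beta = beta, df = df,
      thresholded = FALSE,
      degenerate = if (any(degenerate)) degenerate else matrix(FALSE, 0, 0))
}

#' Clamp negative age effects to zero
#'
#' Thresholding the maturational dense connectome at 0 keeps only
#' age-dependent *increases* in correlation for network estimation. The dense
#' shape is preserved (negatives become 0, nothing is deleted) and the
#' operation is idempotent; +/-Inf sentinels are zeroed with a warning so
#' factorisation inputs stay finite.
#'
#' @param m a [MaturationalDense-class], not already thresholded.
#' @return the thresholded [MaturationalDense-class].
#' @export
thresholdPositive <- function(m) {
  stopifnot(is(m, "MaturationalDense"))
  if (m@thresholded) stop("matrix is already thresholded")
  tv <- m@tValues
  if (any(is.infinite(tv))) {
    warning("excluding ", sum(is.infinite(tv)),
            " infinite t sentinel(s) from the thresholded matrix")
    tv[is.infinite(tv)] <- 0
  }
  tv[tv < 0] <- 0
  new("MaturationalDense", tValues = tv, beta = m@beta, df = m@df,
      thresholded = TRUE, degenerate = m@degenerate)
}

#' Run the connectome stage over a cohort of series
#'
#' Convenience wrapper chaining [denseConnectome()] per subject (streamed)
#' into [fitAgeEffect()].
#'
#' @param seriesList list of [MaskedSeries-class], in cohort order.
#' @param cohort a [CohortTable-class].
#' @param fisher see [fitAgeEffect()].
#' @return a [MaturationalDense-class].
#' @export
maturationalDense <- function(seriesList, cohort, fisher = FALSE) {
  stopifnot(length(seriesList) == length(cohort@age))
  fitAgeEffect(function(i) denseConnectome(seriesList[[i]]), cohort,
               fisher = fisher)
}
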