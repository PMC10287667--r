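#' @include AllClasses.R
NULL

#' Optimal one-to-one assignment (Hungarian algorithm)
#'
#' Minimises total cost over one-to-one assignments of rows to columns
#' (rectangular matrices allowed; every row of the smaller side is assigned).
#' O(n^3) shortest-augmenting-path implementation with potentials.
#'
#' @param cost numeric cost matrix.
#' @return integer vector: for each row, the assigned column (0 when the
#'   matrix has more rows than columns and the row is unassigned).
#' @export
hungarianAssignment <- function(cost) {
  stopifnot(is.matrix(cost), all(is.finite(cost)))
  transposed <- FALSE
  if (nrow(cost) > ncol(cost)) { cost <- t(cost); transposed <- TRUE }
  n <- nrow(cost); m <- ncol(cost)
  u <- numeric(n)
  v <- numeric(m + 1)
  p <- integer(m + 1)                    # p[j+1]: row matched to column j
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, m + 1)
    used <- logical(m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          if (p[j + 1] > 0L) u[p[j + 1]] <- u[p[j + 1]] + delta
          v[j + 1] <- v[j + 1] - delta
        } else minv[j + 1] <- minv[j + 1] - delta
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignRow <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0L) assignRow[p[j + 1]] <- j
  if (!transposed) return(assignRow)
  out <- integer(m)                      # original rows = current columns
  out[assignRow] <- seq_len(n)
  out
}

#' Match estimated maps to ground-truth maps
#'
#' Optimal one-to-one assignment on absolute spatial Pearson correlation
#' (insensitive to ICA sign and order indeterminacy). If fewer estimates than
#' truth maps are supplied, a partial matching is returned and flagged.
#'
#' @param estimated a [SpatialMapSet-class] or M x N matrix of estimated maps.
#' @param truthMaps a [SpatialMapSet-class], [TruthSpec-class] or P x N matrix
#'   of ground-truth maps.
#' @return a data.frame with one row per truth map: `truth`, `estimate`
#'   (NA when unmatched), `absR`. Attribute `partial` is TRUE when
#'   M < P.
#' @export
scoreRecovery <- function(estimated, truthMaps) {
  est <- if (is(estimated, "SpatialMapSet")) estimated@maps else estimated
  tru <- if (is(truthMaps, "SpatialMapSet")) truthMaps@maps
         else if (is(truthMaps, "TruthSpec")) truthMaps@networkMaps
         else truthMaps
  if (nrow(tru) < 1L) stop("need at least one truth map")
  absR <- abs(stats::cor(t(tru), t(est)))        # P x M
  assign <- hungarianAssignment(1 - absR)        # per truth row
  p <- nrow(tru)
  partial <- nrow(est) < p
  if (partial)
    warning("fewer estimated maps (", nrow(est), ") than truth maps (", p,
            "); partial matching")
  out <- data.frame(truth = seq_len(p),
                    estimate = ifelse(assign == 0L, NA_integer_, assign),
                    absR = NA_real_)
  ok <- !is.na(out$estimate)
  out$absR[ok] <- absR[cbind(out$truth[ok], out$estimate[ok])]
  attr(out, "partial") <- partial
  out
}

#' Permutation null for matched spatial correlations
#'
#' Distribution of the best-matched mean |r| when the estimated maps carry no
#' spatial structure related to the truth: each permutation spatially
#' shuffles the estimated maps' voxels and re-matches.
#'
#' @param estimated,truthMaps as in [scoreRecovery()].
#' @param nPerm number of permutations (default 99).
#' @param seed RNG seed.
#' @return numeric vector of null mean matched |r| values.
#' @export
matchedCorrelationNull <- function(estimated, truthMaps, nPerm = 99L,
                                   seed = 1L) {
  est <- if (is(estimated, "SpatialMapSet")) estimated@maps else estimated
  oldSeed <- globalSeed()
  on.exit(restoreSeed(oldSeed), add = TRUE)
  set.seed(as.integer(seed))
  vapply(seq_len(nPerm), function(b) {
    perm <- est[, sample.int(ncol(est)), drop = FALSE]
    mean(scoreRecovery(perm, truthMaps)$absR, na.rm = TRUE)
  }, numeric(1))
}
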