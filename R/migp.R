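#' @include AllClasses.R
NULL

#' Incremental block SVD reduction (MIGP-style)
#'
#' Reduces a wide matrix to a low-rank row basis without ever holding the
#' whole matrix as samples. The input is addressed column-block by
#' column-block (columns are samples, rows are the N variables being
#' reduced over). The procedure starts from the first two blocks, reduces to
#' `rKeep` components by SVD, then repeatedly concatenates the next block and
#' re-reduces until all blocks are exhausted. Retained rows are weighted by
#' their singular values so that later SVDs see correctly scaled variance
#' (disable with `weighted = FALSE`).
#'
#' The returned basis spans (approximately, exactly for inputs of rank <=
#' `rKeep`) the top-`rKeep` singular subspace of the full matrix in its row
#' dimension.
#'
#' @param x either a numeric matrix (N rows x columns, split column-wise into
#'   `nBlocks` near-equal blocks in natural order) or a function
#'   `function(i)` returning the i-th column block (N x b_i) for
#'   i in 1..nBlocks.
#' @param nBlocks number of column blocks (>= 1).
#' @param rKeep target rank; capped (with a warning) at the number of sample
#'   rows actually seen.
#' @param weighted weight retained rows by singular values (default TRUE).
#' @return a [ReducedBasis-class] with `components` (R x N) and the retained
#'   singular values.
#' @export
incrementalBlockSVD <- function(x, nBlocks, rKeep, weighted = TRUE) {
  stopifnot(nBlocks >= 1L, rKeep >= 1L)
  if (is.matrix(x)) {
    nc <- ncol(x)
    if (nBlocks > nc) stop("more blocks than columns")
    bnd <- floor(seq(0, nc, length.out = nBlocks + 1))
    getBlock <- function(i) x[, (bnd[i] + 1):bnd[i + 1], drop = FALSE]
  } else if (is.function(x)) {
    getBlock <- x
  } else stop("x must be a matrix or a block-accessor function")

  reduce <- function(w, r) {
    s <- svd(w, nu = 0)
    r <- min(r, sum(s$d > s$d[1] * 1e-12), nrow(w), ncol(w))
    comp <- t(s$v[, seq_len(r), drop = FALSE])
    list(components = if (weighted) s$d[seq_len(r)] * comp else comp,
         d = s$d[seq_len(r)])
  }

  rowsSeen <- 0L
  first <- t(getBlock(1))                        # samples x N
  rowsSeen <- rowsSeen + nrow(first)
  if (nBlocks >= 2L) {
    b2 <- t(getBlock(2))
    rowsSeen <- rowsSeen + nrow(b2)
    first <- rbind(first, b2)
  }
  red <- reduce(first, rKeep)
  w <- red$components
  i <- 3L
  while (i <= nBlocks) {
    bi <- t(getBlock(i))
    rowsSeen <- rowsSeen + nrow(bi)
    red <- reduce(rbind(w, bi), rKeep)
    w <- red$components
    i <- i + 1L
  }
  if (nrow(w) < rKeep)
    warning("requested rank ", rKeep, " not attainable; returning rank ",
            nrow(w))
  # unweighted variant: recover singular values for the record anyway
  new("ReducedBasis", components = w, singularValues = red$d,
      rankKept = nrow(w))
}
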