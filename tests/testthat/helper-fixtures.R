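# Shared in-code fixtures: tiny masks, cohorts and series built at test time.

# small box mask with every voxel in-mask
boxMask <- function(dims = c(4L, 4L, 3L), voxelSize = c(2, 2, 2),
                    mirror = FALSE) {
  gridMask(array(1, dims), voxelSize = voxelSize, mirror = mirror)
}

randomSeries <- function(n, t, id = "sub-001", seed = 1) {
  set.seed(seed)
  new("MaskedSeries", subjectID = id,
      data = matrix(rnorm(n * t), n, t), tr = 1)
}

smallCohort <- function(k = 5, ages = seq(25, 38, length.out = k)) {
  cohortTable(sprintf("sub-%03d", seq_len(k)), ages)
}

# cohort of pure-noise series on a given mask
noiseCohort <- function(mask, k = 5, t = 30, seed = 1) {
  set.seed(seed)
  n <- nVoxels(mask)
  series <- lapply(seq_len(k), function(i)
    new("MaskedSeries", subjectID = sprintf("sub-%03d", i),
        data = matrix(rnorm(n * t), n, t), tr = 1))
  list(cohort = smallCohort(k), series = series)
}

# brute-force per-element OLS t oracle (loop over elements, lm-free algebra)
olsTOracle <- function(yList, age) {
  k <- length(yList)
  n <- nrow(yList[[1]])
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next                 # diagonal is constant by construction
    y <- vapply(yList, function(m) m[i, j], numeric(1))
    fit <- lm(y ~ age)
    s <- summary(fit)$coefficients
    out[i, j] <- if (nrow(s) == 2) s[2, "t value"] else 0
  }
  out
}

# brute-force assignment oracle: enumerate all permutations (n <= 7)
bruteAssignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(n == ncol(cost), n <= 7)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- NULL; bestCost <- Inf
  for (p in perms(seq_len(n))) {
    cc <- sum(cost[cbind(seq_len(n), p)])
    if (cc < bestCost) { bestCost <- cc; best <- p }
  }
  list(assignment = best, cost = bestCost)
}

# recursive flood-fill connected-components oracle (26-connectivity)
floodFillOracle <- function(coords) {
  n <- nrow(coords)
  comp <- integer(n)
  cur <- 0L
  adjacent <- function(a, b) all(abs(a - b) <= 1) && any(a != b)
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      stack <- i
      while (length(stack)) {
        v <- stack[length(stack)]; stack <- stack[-length(stack)]
        if (comp[v] == 0L) {
          comp[v] <- cur
          for (w in seq_len(n))
            if (comp[w] == 0L && adjacent(coords[v, ], coords[w, ]))
              stack <- c(stack, w)
        }
      }
    }
  }
  comp
}

# row-wise z-scoring for constructing map designs in tests
zscoreRowsForTest <- function(m) {
  t(apply(m, 1, function(r) (r - mean(r)) / sqrt(mean((r - mean(r))^2))))
}

# spatial autocorrelation length of in-mask noise: mean lag-1 neighbour
# correlation along the first axis
lag1SpatialCor <- function(series, mask) {
  co <- voxelCoords(mask)
  key <- paste(co[, 1], co[, 2], co[, 3])
  shifted <- match(paste(co[, 1] + 1L, co[, 2], co[, 3]), key)
  ok <- which(!is.na(shifted))
  x <- seriesData(series)
  mean(vapply(ok, function(i) cor(x[i, ], x[shifted[i], ]), numeric(1)))
}
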