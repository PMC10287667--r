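makeThresholded <- function(m) {
  m[m < 0] <- 0
  diag(m) <- 0
  new("MaturationalDense", tValues = m, df = 10L, thresholded = TRUE)
}

test_that("profile regression equals independent per-column OLS, inverts mixtures", {
  set.seed(103)
  m <- 3; n <- 60
  g <- matrix(rnorm(m * n), m, n)
  dense <- matrix(abs(rnorm(n * n)), n, n)
  diag(dense) <- 0
  md <- new("MaturationalDense", tValues = dense, df = 10L,
            thresholded = TRUE)
  gm <- new("SpatialMapSet", maps = g, mixing = matrix(0, 0, 0),
            kind = "matnet")
  prof <- connectivityProfiles(gm, md)
  gdm <- t(g - rowMeans(g))
  for (v in c(1, 20, 47)) {
    oracle <- coef(lm(dense[, v] ~ gdm))[-1]
    expect_equal(prof@slopes[, v], unname(oracle), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  # collinear maps are rejected by name
  gBad <- rbind(g, g[1, ])
  gmBad <- new("SpatialMapSet", maps = gBad, mixing = matrix(0, 0, 0),
               kind = "matnet")
  expect_error(connectivityProfiles(gmBad, md), "collinear")
})

test_that("all-zero columns give zero slopes; M = 1 matches simple regression", {
  set.seed(107)
  n <- 40
  g1 <- matrix(rnorm(n), 1, n)
  dense <- matrix(abs(rnorm(n * n)), n, n); diag(dense) <- 0
  dense[, 5] <- 0
  md <- new("MaturationalDense", tValues = dense, df = 8L, thresholded = TRUE)
  gm <- new("SpatialMapSet", maps = g1, mixing = matrix(0, 0, 0),
            kind = "matnet")
  prof <- connectivityProfiles(gm, md)
  expect_equal(prof@slopes[1, 5], 0)
  for (v in c(1, 17, 33)) {
    oracle <- coef(lm(dense[, v] ~ as.numeric(g1)))[2]
    expect_equal(prof@slopes[1, v], unname(oracle), tolerance = 1e-10)
  }
  expect_error(connectivityProfiles(gm,
    new("MaturationalDense", tValues = dense, df = 8L, thresholded = FALSE)),
    "thresholded")
})

test_that("maturational connectome equals the pairwise Pearson oracle", {
  set.seed(109)
  s <- matrix(rnorm(5 * 200), 5, 200)
  s[2, ] <- s[1, ]                       # identical rows
  prof <- new("ConnectivityProfiles", slopes = s)
  mc <- maturationalConnectome(prof)
  expect_equal(mc@corr[1, 2], 1)
  expect_equal(diag(mc@corr), rep(1, 5))
  for (i in 1:5) for (j in 1:5)
    expect_equal(mc@corr[i, j], cor(s[i, ], s[j, ]), tolerance = 1e-12)
  # orthogonal-after-demeaning rows
  a <- c(rep(1, 100), rep(-1, 100)); b <- c(rep(c(1, -1), 100))
  mo <- maturationalConnectome(new("ConnectivityProfiles",
                                   slopes = rbind(a, b)))
  expect_equal(mo@corr[1, 2], 0, tolerance = 1e-12)
  # zero-variance row flagged
  sz <- rbind(s[1:2, ], rep(2, 200))
  expect_warning(mz <- maturationalConnectome(
    new("ConnectivityProfiles", slopes = sz)), "zero-variance")
  expect_equal(mz@corr[3, 1], 0)
})

test_that("spectral embedding separates two weakly bridged blocks", {
  # 6-node toy: two dense triads, one weak bridge
  w <- matrix(0, 6, 6)
  w[1:3, 1:3] <- 0.9; w[4:6, 4:6] <- 0.9
  w[3, 4] <- w[4, 3] <- 0.1
  diag(w) <- 1
  mc <- new("MatnetConnectome", corr = w, zeroVariance = rep(FALSE, 6))
  emb <- laplacianEmbedding(mc, dim = 3)
  sgn <- sign(emb@coords[, 1])
  expect_true(all(sgn[1:3] == sgn[1]) && all(sgn[4:6] == -sgn[1]))
})

test_that("embedding is equivariant under network permutation", {
  set.seed(113)
  s <- matrix(rnorm(6 * 100), 6, 100) + 2 * matrix(rnorm(6), 6, 100)[, rep(1, 100)] * 0
  base <- abs(cor(t(s))); diag(base) <- 1
  mc <- new("MatnetConnectome", corr = base, zeroVariance = rep(FALSE, 6))
  p <- c(4, 1, 6, 2, 5, 3)
  mcP <- new("MatnetConnectome", corr = base[p, p],
             zeroVariance = rep(FALSE, 6))
  e1 <- laplacianEmbedding(mc)
  e2 <- laplacianEmbedding(mcP)
  for (d in 1:3) {
    agree <- min(max(abs(e2@coords[, d] - e1@coords[p, d])),
                 max(abs(e2@coords[, d] + e1@coords[p, d])))
    expect_lt(agree, 1e-8)
  }
})

test_that("complete equal-weight graph matches the closed-form spectrum", {
  m <- 6
  w <- matrix(0.5, m, m); diag(w) <- 1
  mc <- new("MatnetConnectome", corr = w, zeroVariance = rep(FALSE, m))
  emb <- laplacianEmbedding(mc, dim = 3)
  expect_equal(emb@eigenvalues, rep(m / (m - 1), 3), tolerance = 1e-10)
  expect_equal(crossprod(emb@coords), diag(3), tolerance = 1e-10)
})

test_that("disconnected graphs and isolated nodes are rejected", {
  w <- diag(6)
  w[1:3, 1:3] <- 0.8; w[4:6, 4:6] <- 0.8; diag(w) <- 1
  mc <- new("MatnetConnectome", corr = w, zeroVariance = rep(FALSE, 6))
  expect_error(laplacianEmbedding(mc, dim = 1), "disconnected")
  w2 <- matrix(0.5, 6, 6); w2[6, ] <- w2[, 6] <- -0.2; diag(w2) <- 1
  mc2 <- new("MatnetConnectome", corr = w2, zeroVariance = rep(FALSE, 6))
  expect_error(laplacianEmbedding(mc2, dim = 3), "isolated")
})

test_that("ward partition selects the finest no-singleton cut", {
  set.seed(127)
  cloud1 <- matrix(rnorm(5 * 3, sd = 0.2), 5, 3)
  cloud2 <- matrix(rnorm(5 * 3, sd = 0.2), 5, 3) + 10
  part <- wardPartition(rbind(cloud1, cloud2))
  expect_equal(part@nGroups, 2L)
  expect_length(unique(groupLabels(part)[1:5]), 1L)
  expect_length(unique(groupLabels(part)[6:10]), 1L)

  # brute-force verification of the selection rule on random points
  for (rep in 1:5) {
    x <- matrix(rnorm(sample(4:8, 1) * 3), ncol = 3)
    part <- wardPartition(x)
    hc <- part@linkage
    valid <- vapply(2:nrow(x), function(k)
      min(table(cutree(hc, k = k))) >= 2, logical(1))
    expected <- if (any(valid)) max((2:nrow(x))[valid]) else 1L
    expect_equal(part@nGroups, expected)
  }

  # M = 2: every 2-cut makes singletons, fall back to G = 1
  part2 <- wardPartition(matrix(c(0, 0, 0, 1, 1, 1), 2, 3, byrow = TRUE))
  expect_equal(part2@nGroups, 1L)
})

test_that("hub maps equal the first principal component of each group", {
  set.seed(131)
  n <- 300
  h <- rnorm(n)
  grp <- t(vapply(c(1.0, 0.8, 1.2), function(w) w * h + rnorm(n, sd = 0.05),
                  numeric(n)))
  other <- matrix(rnorm(2 * n), 2, n)
  prof <- new("ConnectivityProfiles", slopes = rbind(grp, other))
  part <- new("GroupPartition", labels = c(1L, 1L, 1L, 2L, 2L),
              nGroups = 2L, linkage = NULL)
  hubs <- hubMaps(prof, part)
  expect_gte(abs(cor(maps(hubs)[1, ], h)), 0.99)
  expect_gte(cor(maps(hubs)[1, ], colMeans(grp)), 0)   # sign convention
  # SVD oracle
  cen <- grp - rowMeans(grp)
  pc1 <- svd(cen)$v[, 1]
  if (sum(pc1 * colMeans(grp)) < 0) pc1 <- -pc1
  expect_equal(maps(hubs)[1, ], pc1, tolerance = 1e-10, ignore_attr = TRUE)
  expect_gt(hubs@varExplained[1], 0.9)

  # identical maps: hub proportional to the map, explained variance 1
  same <- new("ConnectivityProfiles",
              slopes = rbind(h, h, matrix(rnorm(2 * n), 2, n)))
  hs <- hubMaps(same, new("GroupPartition", labels = c(1L, 1L, 2L, 2L),
                          nGroups = 2L, linkage = NULL))
  expect_gte(abs(cor(maps(hs)[1, ], h)), 1 - 1e-8)
})

test_that("coupling trajectories: identity maps couple at 1; planted slope recovered", {
  spec <- truthSpec()
  gen <- generateCohort(spec, K = 24, T_ = 120, seed = 17)
  n <- nVoxels(spec@mask)
  mapA <- 10 * spec@networkMaps[1, ]           # z-like, suprathreshold core
  traj0 <- couplingTrajectory(mapA, mapA, gen$series, gen$cohort,
                              zThresh = 5)
  expect_true(all(abs(traj0@table$coupling - 1) < 1e-12))

  mapB <- 10 * spec@networkMaps[2, ]
  traj <- couplingTrajectory(mapA, mapB, gen$series, gen$cohort, zThresh = 5)
  # coupling grows with age on the planted emerging edge
  expect_gt(cor(traj@table$age, traj@table$coupling), 0.3)
  fit1 <- lm(coupling ~ age, data = traj@table)
  expect_gt(coef(fit1)[2], 0)
  expect_error(couplingTrajectory(mapA, mapB, gen$series, gen$cohort,
                                  zThresh = 100), "threshold error")
})

test_that("age-constant couplings select order 1 with a null slope", {
  # noise-free cohort with a fixed 0.5 coupling at every age: only the
  # finite-T sampling noise of the per-subject correlation remains
  spec <- truthSpec(emergingEdges = matrix(c(1L, 2L), 1),
                    couplingSlopeValue = 0, noiseSd = 0,
                    baselineCoupling = {
                      b <- diag(5); b[1, 2] <- b[2, 1] <- 0.5; b
                    })
  k <- 40
  gen <- generateCohort(spec, K = k, T_ = 300, seed = 23)
  mapA <- 10 * spec@networkMaps[1, ]
  mapB <- 10 * spec@networkMaps[2, ]
  traj <- couplingTrajectory(mapA, mapB, gen$series, gen$cohort, zThresh = 5)
  expect_equal(traj@order, 1L)
  slope <- summary(traj@fit)$coefficients[2, ]
  expect_lt(abs(slope["Estimate"]), 2 * slope["Std. Error"])
})

test_that("dendrograms serialise to nested-list JSON", {
  part <- wardPartition(matrix(rnorm(12), 4, 3))
  js <- dendrogramJson(part)
  parsed <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_true(!is.null(parsed$height))
  leaves <- function(nd) {
    if (!is.null(nd$leaf)) return(nd$leaf)
    unlist(lapply(nd$children, leaves))
  }
  expect_setequal(unlist(leaves(parsed)), 1:4)
})
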