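test_that("seed-to-brain maps match the loop-based oracle", {
  set.seed(139)
  k <- 10; n <- 5; t <- 25
  cohort <- smallCohort(k)
  series <- lapply(seq_len(k), function(i)
    new("MaskedSeries", subjectID = sprintf("s%d", i),
        data = matrix(rnorm(n * t), n, t), tr = 1))
  sb <- seedToBrain(series, cohort, seedVoxels = c(2L, 4L))
  subj <- matrix(0, k, n)
  for (i in seq_len(k)) {
    seedTc <- colMeans(seriesData(series[[i]])[c(2, 4), ])
    for (v in seq_len(n))
      subj[i, v] <- cor(seedTc, seriesData(series[[i]])[v, ])
  }
  expect_equal(sb@groupMean, colMeans(subj), tolerance = 1e-12)
  agev <- ages(cohort)
  for (v in seq_len(n)) {
    oracle <- summary(lm(subj[, v] ~ agev))$coefficients[2, "t value"]
    expect_equal(sb@ageT[v], oracle, tolerance = 1e-10)
  }
  # single-voxel seed: its own group-mean value is exactly 1
  sb1 <- seedToBrain(series, cohort, seedVoxels = 3L)
  expect_equal(sb1@groupMean[3], 1)
})

test_that("zero seed timecourses exclude the subject with a warning", {
  k <- 4
  cohort <- smallCohort(k)
  series <- lapply(seq_len(k), function(i) randomSeries(6, 20, seed = i))
  series[[2]]@data[5, ] <- 0
  expect_warning(sb <- seedToBrain(series, cohort, seedVoxels = 5L),
                 "excluded")
  expect_equal(sb@excluded, "sub-002")
})

test_that("planted seed-target coupling beats the permutation null", {
  spec <- truthSpec()
  gen <- generateCohort(spec, K = 30, T_ = 120, seed = 29)
  seedVox <- which(spec@networkMaps[1, ] > 0.6)
  target <- which(spec@networkMaps[2, ] > 0.6)
  sb <- seedToBrain(gen$series, gen$cohort, seedVox)
  obs <- mean(sb@ageT[target])
  set.seed(30)
  null <- replicate(49, {
    perm <- cohortTable(subjectIDs(gen$cohort), sample(ages(gen$cohort)))
    mean(seedToBrain(gen$series, perm, seedVox)@ageT[target])
  })
  expect_gt(obs, quantile(null, 0.95))
})

test_that("homologous connectivity is symmetric, exact for mirrored data, null for noise", {
  mask <- boxMask(c(4L, 3L, 3L), mirror = TRUE)
  n <- nVoxels(mask)
  co <- voxelCoords(mask)
  set.seed(31)
  # exactly mirror-symmetric series
  half <- matrix(rnorm(n * 30), n, 30)
  dataSym <- half
  for (v in seq_len(n)) dataSym[v, ] <- half[pmin(v, mask@mirrorPair[v]), ]
  sym <- new("MaskedSeries", subjectID = "s", data = dataSym, tr = 1)
  hmap <- homologousConnectivity(sym, mask)
  expect_equal(hmap, rep(1, n), tolerance = 1e-12)

  noise <- randomSeries(n, 200, seed = 32)
  hn <- homologousConnectivity(noise, mask)
  expect_lt(max(abs(hn), na.rm = TRUE), 4 / sqrt(200))
  # the map equals its own mirror image
  expect_equal(hn, hn[mask@mirrorPair], tolerance = 1e-12)
})

test_that("suprathreshold clusters match the flood-fill oracle", {
  mask <- boxMask(c(6L, 6L, 4L))
  n <- nVoxels(mask)
  co <- voxelCoords(mask)
  # two disjoint blobs of 4 and 7 voxels
  m <- rep(0, n)
  blobA <- which(co[, 1] <= 2 & co[, 2] <= 2 & co[, 3] == 1)[1:4]
  blobB <- which(co[, 1] >= 5 & co[, 2] >= 4 & co[, 3] >= 3)[1:7]
  m[blobA] <- 5; m[blobB] <- 4
  cl <- seedsFromAgeMap(m, mask, zPos = 3)
  expect_equal(cl$sizes, c(7L, 4L))
  expect_equal(sum(cl$labels > 0), 11L)

  expect_equal(seedsFromAgeMap(m, mask, zPos = 10)$sizes, integer())

  set.seed(33)
  rmap <- rnorm(n)
  cl2 <- seedsFromAgeMap(rmap, mask, zPos = 0.8)
  oracle <- floodFillOracle(co[rmap > 0.8, , drop = FALSE])
  expect_equal(length(cl2$sizes), max(oracle))
  expect_equal(sort(cl2$sizes), sort(as.integer(table(oracle))))

  # negative thresholding for white-matter-style seeds
  cln <- seedsFromAgeMap(-m, mask, zNeg = -3, negative = TRUE)
  expect_equal(cln$sizes, c(7L, 4L))
})

test_that("parcellation covers the mask and pair counts follow P(P-1)/2", {
  mask <- truthSpec()@mask
  parc <- parcellateMask(mask, P = 40, seed = 3)
  expect_equal(sort(unique(parc@labels)), 1:40)
  expect_equal(length(parc@labels), nVoxels(mask))
  for (p in c(1, 17)) {
    member <- mmCoords(mask)[parc@labels == p, , drop = FALSE]
    expect_equal(parc@centres[p, ], colMeans(member), tolerance = 1e-12)
  }

  spec <- truthSpec()
  gen <- generateCohort(spec, K = 6, T_ = 60, seed = 41)
  ds <- distanceSimilarity(gen$series, gen$cohort, spec@mask, P = 2,
                           seed = 1)
  expect_equal(nrow(ds$pairs), 1L)
  # the distance-dominance mechanism concerns the smearing-driven regime:
  # a noise-dominated cohort where local autocorrelation shapes the
  # correlation structure, while age-effect maps carry only its (noisier)
  # change — so their similarity is less organised by distance
  spec2 <- truthSpec(noiseSd = 3)
  gen2 <- generateCohort(spec2, K = 20, T_ = 80, seed = 42)
  ds2 <- distanceSimilarity(gen2$series, gen2$cohort, spec2@mask, P = 25,
                            seed = 1)
  expect_equal(nrow(ds2$pairs), 25 * 24 / 2)
  expect_lt(ds2$corGroupMean, -0.5)
  expect_gt(ds2$corAgeT, ds2$corGroupMean)
})

test_that("FD summaries have params x stacks columns and recover a planted factor", {
  set.seed(43)
  k <- 30; nP <- 6L; nS <- 16L; t <- 50
  f <- rnorm(k)
  lam <- 0.5 + runif(nP * nS)
  motion <- list()
  ids <- sprintf("m%02d", 1:k)
  for (i in 1:k) {
    sdScale <- lam * (1 + 0.3 * f[i])
    incr <- array(rnorm(nP * nS * t), c(nP, nS, t)) *
      array(sdScale, c(nP, nS, t))
    motion[[ids[i]]] <- aperm(apply(incr, c(1, 2), cumsum), c(2, 3, 1))
  }
  cohort <- cohortTable(ids, seq(25, 38, length.out = k), motion = motion)
  fd <- fdGlobal(cohort, nParams = nP, nStacks = nS)
  expect_equal(dim(fd@summary), c(k, 96L))
  expect_gte(abs(cor(fd@scores, f)), 0.95)
  # sign convention: PC1 tracks overall motion positively
  expect_gt(cor(fd@scores, rowMeans(fd@summary)), 0)

  # identical traces across subjects: informative degenerate-input error
  same <- lapply(ids[1:3], function(i) motion[[1]])
  names(same) <- ids[1:3]
  cohort2 <- cohortTable(ids[1:3], c(25, 30, 35), motion = same)
  expect_error(fdGlobal(cohort2, nP, nS), "zero variance")
})
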