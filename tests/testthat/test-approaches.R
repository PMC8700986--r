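test_that("correlation neighbour ranking matches brute force", {
  set.seed(25)
  ds <- makeTinySet(n = 31, p = 12, seed = 25)
  X <- spectraMatrix(ds)
  sel <- selectNeighboursShenk(ds, "s01", k = 5)
  rAll <- sapply(2:31, function(j) cor(X[1, ], X[j, ]))
  expect_identical(sel@neighbourIds,
                   colnames(ds)[-1][order(-rAll)][1:5])
  expect_equal(sel@values, sort(rAll, decreasing = TRUE)[1:5])
  expect_false("s01" %in% sel@neighbourIds)
  expect_error(selectNeighboursShenk(ds, "s01", k = 30), "smaller")
})

test_that("identical and affine-transformed spectra rank first", {
  ds <- makeTinySet(n = 20, p = 10, seed = 26)
  m <- spectraMatrix(ds)
  m[5, ] <- m[1, ]                    # identical twin
  m[9, ] <- 3 * m[1, ] + 2            # positive affine transform
  ds2 <- SpectraSet(m, wavenumbers(ds), colnames(ds), animalIds(ds),
                    traitTable(ds))
  sel <- selectNeighboursShenk(ds2, "s01", k = 3)
  expect_setequal(sel@neighbourIds[1:2], c("s05", "s09"))
  expect_equal(sel@values[1:2], c(1, 1))
  # zero-variance candidate is excluded with a warning
  m[12, ] <- 1
  ds3 <- SpectraSet(m, wavenumbers(ds), colnames(ds), animalIds(ds),
                    traitTable(ds))
  expect_warning(sel3 <- selectNeighboursShenk(ds3, "s01", k = 18),
                 "zero-variance")
  expect_false("s12" %in% sel3@neighbourIds)
})

test_that("changepoint rule takes the first changepoint of at least 20", {
  # planted distance profile: level changes after candidates 5 and 30
  values <- c(rep(1, 5), rep(2, 25), rep(5, 30))
  ds <- makeDistanceSet(values, seed = 27)
  cfg <- approachConfig("local_changepoint", nPcs = 1)
  # the engineered profile really has changepoints at 5 and 30
  sp <- fitPCSpace(spectraMatrix(ds), standardise = TRUE, nComponents = 1)
  dAll <- sort(mahalanobisToAll(sp, projectScores(sp, ds), 1)[-1])
  fit <- detectPELT(dAll, penalty = cfg$penalty)
  expect_identical(fit@changepoints, c(5L, 30L))
  # ... and the rule skips 5 (< 20) in favour of 30
  sel <- selectNeighboursChangepoint(ds, "s001", cfg)
  expect_equal(sel@rule, "changepoint")
  expect_equal(length(sel@neighbourIds), 30L)
  expect_equal(sel@changepointIndex, 30L)
  expect_lt(sel@values[5], sel@values[6])
})

test_that("flat distance profiles fall back to all candidates", {
  # 25 identical candidates: every distance is equal, no mean change exists
  set.seed(28)
  prof <- runif(10, 0.5, 1.5)
  spectra <- rbind(2 * prof, matrix(rep(prof, 25), 25, byrow = TRUE))
  ds <- SpectraSet(spectra + 0, seq(1000, by = 20, length.out = 10),
                   sprintf("s%02d", 1:26), sprintf("a%02d", 1:26),
                   data.frame(y = rnorm(26)))
  cfg <- approachConfig("local_changepoint", nPcs = 1,
                        varianceMode = "fixed_one")
  expect_warning(sel <- selectNeighboursChangepoint(ds, "s01", cfg),
                 "all candidates")
  expect_equal(sel@rule, "all")
  expect_equal(length(sel@neighbourIds), 25L)
})

test_that("neighbour counts vary across predictands on structured data", {
  ds <- plantedNeighbourFixture(40, 80, 10, seed = 29)
  counts <- sapply(colnames(ds), function(id)
    length(suppressWarnings(
      selectNeighboursChangepoint(ds, id))@neighbourIds))
  expect_gt(length(unique(counts)), 1)
  expect_true(all(counts >= 20))
})

test_that("noiseless linear traits are predicted exactly by the global fit", {
  set.seed(30)
  n <- 25; p <- 10
  X <- matrix(rnorm(n * p), n) + 2
  beta <- rnorm(p)
  ds <- SpectraSet(X, seq(1000, by = 30, length.out = p),
                   sprintf("s%02d", 1:n), sprintf("a%02d", 1:n),
                   data.frame(y = drop(X %*% beta)))
  for (id in colnames(ds)[1:5]) {
    pr <- predictTrait(ds, id, "y", approachConfig("global", maxFactors = 10))
    expect_lt(abs(pr - traitTable(ds)[id, "y"]), 1e-6)
  }
})

test_that("local changepoint exploits planted cluster structure", {
  # two tight clusters along one latent axis; the trait slope on the second
  # axis flips sign between clusters, so only within-cluster models work
  set.seed(31)
  n <- 120; p <- 40
  cl <- rep(1:2, each = n / 2)
  z1 <- ifelse(cl == 1, -10, 10) + rnorm(n)
  z2 <- runif(n, -sqrt(3), sqrt(3))   # bounded: no sparse tails to bridge
  latent <- cbind(z1, z2)
  X <- latent %*% matrix(rnorm(2 * p), 2) + matrix(rnorm(n * p, sd = 1e-3), n)
  y <- ifelse(cl == 1, 1, -1) * z2 * 5 + rnorm(n, sd = 0.3)
  ds <- SpectraSet(X, seq(1000, by = 10, length.out = p),
                   sprintf("s%03d", 1:n), sprintf("a%03d", 1:n),
                   data.frame(y = y))
  ids <- colnames(ds)
  cfgCP <- approachConfig("local_changepoint", nPcs = 2)
  idx <- seq(1, n, by = 5)
  predL <- numeric(length(idx)); predG <- numeric(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    det <- predictTrait(ds, ids[i], "y", cfgCP, details = TRUE)
    # well-separated clusters: neighbour sets stay within the cluster
    expect_true(all(cl[match(det$trainingIds, ids)] == cl[i]))
    predL[j] <- det$prediction
    predG[j] <- predictTrait(ds, ids[i], "y", approachConfig("global"))
  }
  expect_lt(rmsev(y[idx], predL), rmsev(y[idx], predG))
})

test_that("LOCAL predictions run end to end with finite results", {
  cfg <- syntheticConfig(nSamples = 100, nWavelengths = 50, seed = 32)
  ds <- generateSpectra(cfg)
  cfgS <- approachConfig("local_shenk", shenkK = 25, shenkFactors = 5)
  preds <- sapply(colnames(ds)[1:10], function(id)
    predictTrait(ds, id, "ph", cfgS))
  expect_true(all(is.finite(preds)))
})

test_that("no predictand's trait value reaches its own training set", {
  cfg <- syntheticConfig(nSamples = 60, nWavelengths = 40, seed = 33)
  ds <- generateSpectra(cfg)
  ids <- colnames(ds)
  configs <- list(approachConfig("global", maxFactors = 10),
                  approachConfig("local_shenk", shenkK = 25),
                  approachConfig("local_changepoint"))
  for (cfgA in configs) {
    for (id in ids[seq(1, 60, by = 12)]) {
      det <- predictTrait(ds, id, "ph", cfgA, details = TRUE)
      expect_false(id %in% det$trainingIds)
    }
  }
})

test_that("excluding the predictand from the PC fit still selects sensibly", {
  ds <- plantedNeighbourFixture(40, 80, 10, seed = 48)
  core <- S4Vectors::metadata(ds)$planted$coreIds
  strict <- approachConfig("local_changepoint",
                           pcFitScope = "exclude_predictand")
  selStrict <- suppressWarnings(selectNeighboursChangepoint(ds, core[2],
                                                            strict))
  selFull <- suppressWarnings(selectNeighboursChangepoint(ds, core[2]))
  # the strict geometry must recover the same planted core neighbourhood
  expect_setequal(selStrict@neighbourIds, selFull@neighbourIds)
  expect_setequal(selStrict@neighbourIds, setdiff(core, core[2]))
})
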