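test_that("absorbance transform is log10(1/T) and rejects T <= 0", {
  expect_equal(toAbsorbance(matrix(c(1, 0.1, 0.01), 1)),
               matrix(c(0, 1, 2), 1))
  ds <- makeTinySet(units = "transmittance")
  ab <- toAbsorbance(ds)
  expect_equal(spectraUnits(ab), "absorbance")
  expect_equal(spectraMatrix(ab), log10(1 / spectraMatrix(ds)),
               ignore_attr = TRUE)
  # strictly decreasing in T
  tv <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(toAbsorbance(matrix(tv, 1))[1, ]) < 0))

  m <- spectraMatrix(ds); m[4, 2] <- 0
  bad <- SpectraSet(m, wavenumbers(ds), colnames(ds), animalIds(ds),
                    traitTable(ds), units = "transmittance")
  expect_error(toAbsorbance(bad), "s04")
})

test_that("region trimming drops exactly the windowed wavelengths", {
  grid <- c(1500, 1600, 1700, 1800)
  ds <- SpectraSet(matrix(runif(8), 2), grid, c("a", "b"), c("a", "b"))
  suppressMessages(out <- trimRegions(ds, list(c(1580, 1710))))
  expect_equal(wavenumbers(out), c(1500, 1800))

  ds2 <- makeTinySet()
  suppressMessages(expect_equal(
    wavenumbers(trimRegions(ds2, list())), wavenumbers(ds2)))

  # conventional three windows on a coarse full grid, against brute force
  grid <- seq(900, 4000, by = 10)
  wins <- list(c(1580, 1710), c(2990, 3690), c(3822, Inf))
  keepExpected <- sapply(grid, function(w)
    !((w >= 1580 && w <= 1710) || (w >= 2990 && w <= 3690) || w > 3822))
  ds3 <- SpectraSet(matrix(runif(2 * length(grid)), 2), grid,
                    c("a", "b"), c("a", "b"))
  suppressMessages(out3 <- trimRegions(ds3, wins))
  expect_equal(wavenumbers(out3), grid[keepExpected])
  # idempotent under the same windows
  suppressMessages(expect_equal(wavenumbers(trimRegions(out3, wins)),
                                wavenumbers(out3)))
  expect_error(suppressMessages(trimRegions(ds3, list(c(0, Inf)))),
               "every wavelength")
})

test_that("trait outlier rule drops >3 SD points then incomplete samples", {
  set.seed(11)
  vals <- c(rnorm(19), 50)
  n <- 20
  ds <- SpectraSet(matrix(runif(n * 5), n), 1:5 * 100,
                   sprintf("s%02d", 1:n), sprintf("a%02d", 1:n),
                   data.frame(ph = vals))
  # direct mean/SD computation says only the planted value exceeds 3 SD
  expect_equal(which(abs(vals - mean(vals)) > 3 * sd(vals)), 20L)
  suppressMessages(out <- removeTraitOutliers(ds))
  expect_equal(colnames(out), sprintf("s%02d", 1:19))

  # all-identical trait: no removals
  ds2 <- SpectraSet(matrix(runif(20), 4), 1:5 * 100, letters[1:4],
                    letters[1:4], data.frame(ph = rep(6.6, 4)))
  suppressMessages(expect_equal(ncol(removeTraitOutliers(ds2)), 4L))

  # missing value triggers the completeness rule even when inside 3 SD
  ds3 <- makeTinySet(n = 10)
  cd <- SummarizedExperiment::colData(ds3)
  cd$ph[4] <- NA
  SummarizedExperiment::colData(ds3) <- cd
  suppressMessages(out3 <- removeTraitOutliers(ds3))
  expect_false("s04" %in% colnames(out3))
  expect_equal(ncol(out3), 9L)
})

test_that("deduplication keeps the most PC-space-extreme record", {
  ds <- makeTinySet(n = 20, p = 10, seed = 3)
  suppressMessages(expect_identical(colnames(deduplicateAnimals(ds)),
                                    colnames(ds)))  # all unique: identity

  # plant one animal with a central and an extreme record
  m <- spectraMatrix(ds)
  m[2, ] <- colMeans(m)                 # record at the spectral centre
  m[7, ] <- colMeans(m) + 6 * apply(m, 2, sd)  # far record
  an <- animalIds(ds); an[7] <- an[2]
  ds2 <- SpectraSet(m, wavenumbers(ds), colnames(ds), an, traitTable(ds))
  space <- fitPCSpace(m, standardise = TRUE, nComponents = 4)
  d <- mahalanobisFromCentre(space, projectScores(space, m))
  expect_gt(d[7], d[2])                 # oracle: distances computed directly
  suppressMessages(out <- deduplicateAnimals(ds2))
  expect_true("s07" %in% colnames(out))
  expect_false("s02" %in% colnames(out))

  # two duplicated animals: exactly two fewer rows
  an2 <- animalIds(ds); an2[5] <- an2[4]; an2[11] <- an2[10]
  ds3 <- SpectraSet(spectraMatrix(ds), wavenumbers(ds), colnames(ds), an2,
                    traitTable(ds))
  suppressMessages(expect_equal(ncol(deduplicateAnimals(ds3)),
                                ncol(ds) - 2L))
})

test_that("editing pipeline runs in fixed order and is idempotent", {
  cfg <- syntheticConfig(nSamples = 40, nWavelengths = 60,
                         duplicateAnimalFraction = 0.1,
                         outlierFraction = 0.1, seed = 5)
  ds <- generateSpectra(cfg)
  suppressMessages(edited <- editSpectra(ds))
  expect_true(!anyDuplicated(animalIds(edited)))
  expect_false(anyNA(as.matrix(traitTable(edited))))
  expect_equal(spectraUnits(edited), "absorbance")
  suppressMessages(again <- editSpectra(edited))
  expect_identical(colnames(again), colnames(edited))
  expect_equal(spectraMatrix(again), spectraMatrix(edited))
})
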