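test_that("segment cost matches the naive two-pass computation", {
  expect_equal(segmentCost(rep(3, 7), 1, 7, 1), 0)
  expect_equal(segmentCost(c(0, 2), 1, 2, 1), 2)
  set.seed(7)
  y <- rnorm(40)
  for (k in 1:10) {
    s <- sample(40, 1); t <- s + floor(runif(1) * (41 - s))
    s2 <- runif(1, 0.5, 2)
    expect_equal(segmentCost(y, s, t, s2), oracleSegCost(y, s, t, s2, FALSE))
  }
  expect_error(segmentCost(y, 1, 5, 0), "sigma2")
})

test_that("variance estimators behave as specified", {
  set.seed(8)
  y <- rnorm(10000)
  expect_lt(abs(estimateSigma2(y, "difference_estimator") - 1), 0.05)
  expect_equal(estimateSigma2(y, "fixed_one"), 1)
  expect_equal(estimateSigma2(y, "global_mle"), mean((y - mean(y))^2))
  # difference estimator is robust to a mean shift, the global MLE is not
  ys <- c(rnorm(500), rnorm(500) + 10)
  expect_lt(abs(estimateSigma2(ys, "difference_estimator") - 1), 0.3)
  expect_gt(estimateSigma2(ys, "global_mle"), 10)
  expect_warning(v <- estimateSigma2(rep(2, 50)), "floored")
  expect_gt(v, 0)
})

test_that("AMOC finds the planted split and matches exhaustive search", {
  y <- c(rep(0, 20), rep(5, 20))
  fit <- detectAMOC(y, penalty = "SIC", sigma2 = 1)
  expect_equal(fit@changepoints, 20L)
  expect_length(detectAMOC(rep(1, 30), penalty = "SIC",
                           varianceMode = "fixed_one")@changepoints, 0)
  set.seed(9)
  for (k in 1:40) {
    n <- sample(10:50, 1)
    y <- rnorm(n) + rep(c(0, sample(0:4, 1)), c(floor(n / 2), ceiling(n / 2)))
    for (pen in c("SIC", "MBIC")) {
      s2 <- estimateSigma2(y, "difference_estimator")
      fit <- detectAMOC(y, penalty = pen, sigma2 = s2)
      expect_identical(fit@changepoints,
                       as.integer(oracleAMOC(y, 2 * log(n) *
                                               (1 + (pen == "MBIC") / 2),
                                             s2, pen == "MBIC")))
    }
  }
})

test_that("PELT recovers planted blocks and handles constant input", {
  y <- rep(c(0, 8, 0), each = 30)
  expect_equal(detectPELT(y, penalty = "SIC", sigma2 = 1)@changepoints,
               c(30L, 60L))
  expect_equal(oraclePartition(y, 2 * log(90), 1, FALSE), c(30, 60))
  expect_length(detectPELT(rep(2, 40),
                           varianceMode = "fixed_one")@changepoints, 0)
})

test_that("PELT equals the no-pruning dynamic programme on random vectors", {
  set.seed(10)
  for (k in 1:60) {
    n <- sample(8:50, 1)
    nBlocks <- sample(1:4, 1)
    means <- cumsum(c(0, sample(c(-6, -3, 3, 6), nBlocks - 1,
                                replace = TRUE)))
    sizes <- as.vector(stats::rmultinom(1, n - 2 * nBlocks,
                                        rep(1, nBlocks))) + 2
    y <- rnorm(sum(sizes)) + rep(means, sizes)
    n <- length(y)
    for (pen in c("SIC", "MBIC")) {
      mbic <- pen == "MBIC"
      beta <- if (mbic) 3 * log(n) else 2 * log(n)
      for (vm in c("difference_estimator", "fixed_one", "global_mle")) {
        s2 <- estimateSigma2(y, vm)
        fit <- detectPELT(y, penalty = pen, sigma2 = s2)
        expect_identical(fit@changepoints,
                         as.integer(oraclePartition(y, beta, s2, mbic)))
      }
    }
  }
})

test_that("PELT solution cost beats arbitrary segmentations", {
  set.seed(12)
  y <- rnorm(60) + rep(c(0, 4, -2), each = 20)
  s2 <- 1
  fit <- detectPELT(y, penalty = "SIC", sigma2 = s2)
  totalCost <- function(tau) {
    bounds <- c(0, tau, length(y))
    sum(sapply(seq_len(length(bounds) - 1), function(j)
      segmentCost(y, bounds[j] + 1, bounds[j + 1], s2))) +
      length(tau) * fit@penaltyValue
  }
  best <- totalCost(fit@changepoints)
  for (k in 1:30) {
    m <- sample(0:4, 1)
    tau <- sort(sample(seq(2, 58, by = 2), m))
    expect_gte(totalCost(tau) + 1e-9, best)
  }
})

test_that("segmentation respects penalty monotonicity and scale invariance", {
  set.seed(13)
  y <- rnorm(80) + rep(c(0, 2, 5, 1), each = 20)
  # raising sigma2 scales the cost down, equivalent to a stiffer penalty
  nCps <- sapply(c(0.25, 0.5, 1, 2, 4, 16), function(s2)
    length(detectPELT(y, penalty = "SIC", sigma2 = s2)@changepoints))
  expect_true(all(diff(nCps) <= 0))
  # scaling y by c and sigma2 by c^2 leaves the segmentation unchanged
  for (cc in c(0.1, 3, 50)) {
    expect_identical(
      detectPELT(y * cc, penalty = "MBIC", sigma2 = cc^2)@changepoints,
      detectPELT(y, penalty = "MBIC", sigma2 = 1)@changepoints)
  }
})
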