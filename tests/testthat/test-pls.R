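test_that("noiseless low-rank responses are fitted exactly", {
  set.seed(14)
  n <- 50; p <- 15
  scores <- matrix(rnorm(n * 3), n)        # 3 latent X-directions
  X <- scores %*% matrix(rnorm(3 * p), 3)
  y <- drop(scores %*% rnorm(3))           # y linear in the latent scores
  m <- fitPLS(X, y, 3)
  expect_lt(max(abs(predict(m, X) - y)), 1e-8)
})

test_that("full-rank PLS equals least squares; rank errors are named", {
  set.seed(15)
  X <- matrix(rnorm(40 * 12), 40)
  y <- drop(X %*% rnorm(12)) + rnorm(40)
  m <- fitPLS(X, y, 12)
  ols <- stats::lm.fit(cbind(1, X), y)
  Xnew <- matrix(rnorm(10 * 12), 10)
  expect_lt(max(abs(predict(m, Xnew) -
                    drop(cbind(1, Xnew) %*% ols$coefficients))), 1e-8)
  # rank-2 predictors cannot support 4 factors
  Xr <- matrix(rnorm(30 * 2), 30) %*% matrix(rnorm(2 * 8), 2)
  expect_error(fitPLS(Xr, rnorm(30), 4), "rank is 2")
  expect_error(fitPLS(X, rep(1, 40), 3), "zero-variance")
  expect_error(fitPLS(X, y, 13), "exceeds")
})

test_that("fit and predict match the mixOmics reference implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(16)
  for (k in 1:8) {
    n <- sample(25:45, 1); p <- sample(8:20, 1)
    A <- sample(2:min(6, p), 1)
    X <- matrix(rnorm(n * p), n,
                dimnames = list(NULL, paste0("w", seq_len(p))))
    y <- drop(X %*% rnorm(p)) + rnorm(n)
    Xn <- matrix(rnorm(8 * p), 8,
                 dimnames = list(NULL, paste0("w", seq_len(p))))
    m <- fitPLS(X, y, A)
    ref <- mixOmics::pls(X, y, ncomp = A, scale = FALSE,
                         mode = "regression")
    pref <- predict(ref, Xn)$predict[, 1, A]
    mine <- predict(m, Xn)
    expect_lt(max(abs(mine - pref)) / max(abs(pref)), 1e-6)
  }
})

test_that("prediction is affine in the coefficient path", {
  set.seed(17)
  X <- matrix(rnorm(30 * 10), 30)
  y <- drop(X %*% rnorm(10)) + rnorm(30)
  m <- fitPLS(X, y, 5)
  expect_equal(predict(m, m@xCenter), m@yCenter)
  # direct computation from the stored path
  x <- rnorm(10)
  for (a in 1:5)
    expect_equal(predict(m, x, nFactors = a),
                 m@yCenter + sum((x - m@xCenter) * m@coefficients[, a]))
  expect_error(predict(m, rnorm(4)), "wavelength")
})

test_that("prediction is invariant to column reordering and constant columns", {
  set.seed(18)
  X <- matrix(rnorm(35 * 9), 35)
  y <- drop(X %*% rnorm(9)) + rnorm(35)
  Xn <- matrix(rnorm(6 * 9), 6)
  base <- predict(fitPLS(X, y, 4), Xn)
  perm <- sample(9)
  expect_equal(predict(fitPLS(X[, perm], y, 4), Xn[, perm]), base,
               tolerance = 1e-10)
  expect_equal(predict(fitPLS(cbind(X, 2), y, 4), cbind(Xn, 2)), base,
               tolerance = 1e-10)
})

test_that("LOO CV selects the planted factor count and respects ties", {
  set.seed(19)
  n <- 60; p <- 12
  scores <- matrix(rnorm(n * 3), n)
  X <- scores %*% matrix(rnorm(3 * p), 3)   # noiseless rank-3 structure
  y <- drop(scores %*% c(2, -1, 1))
  cv <- selectFactorsLOOCV(X, y, maxFactors = 8)
  expect_equal(cv@chosenFactors, 3L)
  expect_lt(cv@rmsecv[3], 1e-6)
  expect_equal(selectFactorsLOOCV(X, y, maxFactors = 1)@chosenFactors, 1L)
  # pure-noise responses keep the chosen count small most of the time
  small <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    Xn <- matrix(rnorm(30 * 10), 30)
    yn <- rnorm(30)
    small <- small + (selectFactorsLOOCV(Xn, yn, 8)@chosenFactors <= 3)
  }
  expect_gte(small, 16)
})

test_that("pair-deleted global LOO equals the naive fit-per-fold route", {
  set.seed(20)
  n <- 30; p <- 12; A <- 6
  X <- matrix(rnorm(n * p), n)
  y <- drop(X %*% rnorm(p)) + rnorm(n)
  g <- globalLooPredict(X, y, maxFactors = A)
  naive <- sapply(seq_len(n), function(i) {
    cv <- selectFactorsLOOCV(X[-i, ], y[-i], maxFactors = A)
    predict(fitPLS(X[-i, ], y[-i], cv@chosenFactors), X[i, ])
  })
  expect_lt(max(abs(g$pred - naive)), 1e-8)
  chosen <- sapply(seq_len(n), function(i)
    selectFactorsLOOCV(X[-i, ], y[-i], maxFactors = A)@chosenFactors)
  expect_identical(g$chosenFactors, as.integer(chosen))
  # wide predictors go through the row-space rotation
  Xw <- matrix(rnorm(20 * 40), 20)
  yw <- drop(Xw %*% rnorm(40)) + rnorm(20)
  gw <- globalLooPredict(Xw, yw, maxFactors = 5)
  naivew <- sapply(seq_len(20), function(i) {
    cv <- selectFactorsLOOCV(Xw[-i, ], yw[-i], maxFactors = 5)
    predict(fitPLS(Xw[-i, ], yw[-i], cv@chosenFactors), Xw[i, ])
  })
  expect_lt(max(abs(gw$pred - naivew)), 1e-8)
})

test_that("PLS models serialise to text and back", {
  set.seed(24)
  X <- matrix(rnorm(25 * 7), 25)
  y <- rnorm(25)
  m <- fitPLS(X, y, 3, trainingIds = sprintf("t%02d", 1:25))
  f <- tempfile()
  writePLSModel(m, f)
  back <- readPLSModel(f)
  expect_equal(back@coefficients, m@coefficients, tolerance = 1e-14)
  expect_equal(back@trainingIds, m@trainingIds)
  expect_equal(predict(back, X[3, ]), predict(m, X[3, ]), tolerance = 1e-12)
})
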