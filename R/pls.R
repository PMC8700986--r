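#' Fit a single-response PLS regression
#'
#' Deterministic NIPALS (orthogonal-scores) PLS1 on centred predictors and
#' response.  Predictors are centred but not scaled: any standardisation in
#' this workflow belongs to the neighbour-selection geometry, not to the
#' regression.  With \code{nFactors} equal to the rank of the centred
#' predictor matrix, predictions coincide with the least-squares solution.
#'
#' @param X numeric matrix, samples x wavelengths.
#' @param y numeric response vector.
#' @param nFactors number of latent factors, \code{<= min(n - 1, p)}.
#' @param trainingIds optional identifiers stored with the model.
#' @return A \linkS4class{PLSModel}; its \code{coefficients} slot holds the
#'   whole path, one column per factor count up to \code{nFactors}.
#' @export
fitPLS <- function(X, y, nFactors, trainingIds = character(0)) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (n < nFactors + 1)
    stop("need at least nFactors + 1 training samples")
  if (sd(y) == 0) stop("zero-variance response")
  if (nFactors > min(n - 1, p))
    stop(sprintf("nFactors (%d) exceeds min(n - 1, p) = %d", nFactors,
                 min(n - 1, p)))
  f <- pls_fit_cpp(X, y, as.integer(nFactors))
  if (f$nEffective < nFactors)
    stop(sprintf("requested %d factors but predictor rank is %d", nFactors,
                 f$nEffective))
  new("PLSModel", xCenter = drop(f$xCenter), xScale = rep(1, p),
      yCenter = f$yCenter, nFactors = as.integer(nFactors),
      coefficients = f$coefficients,
      trainingIds = as.character(trainingIds))
}

#' Predict from a fitted PLS model
#'
#' \code{yhat = yCenter + ((x - xCenter) / xScale) \%*\% coefficients[, a]}.
#'
#' @param object a \linkS4class{PLSModel}.
#' @param newdata numeric matrix (samples x wavelengths) or a single
#'   spectrum vector.
#' @param nFactors factor count to predict with (default: the fitted count).
#' @return numeric vector of predictions.
#' @export
setMethod("predict", "PLSModel", function(object, newdata,
                                          nFactors = object@nFactors) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object@xCenter))
    stop("wavelength count does not match the model")
  stopifnot(nFactors >= 1, nFactors <= object@nFactors)
  Z <- sweep(sweep(newdata, 2, object@xCenter), 2, object@xScale, "/")
  drop(object@yCenter + Z %*% object@coefficients[, nFactors])
})

#' @export
setMethod("show", "PLSModel", function(object) {
  cat("PLSModel:", object@nFactors, "factors over",
      length(object@xCenter), "wavelengths,",
      length(object@trainingIds), "training samples\n")
})

#' Choose the PLS factor count by leave-one-out cross-validation
#'
#' For each factor count a = 1..maxFactors, RMSECV(a) is the root mean
#' squared error of predicting each sample from a model fitted on the
#' remaining ones.  The chosen count minimises RMSECV, ties broken toward
#' parsimony (the smallest count).
#'
#' @param X numeric matrix, samples x wavelengths.
#' @param y numeric response.
#' @param maxFactors largest factor count to try,
#'   \code{<= min(n - 2, p)}; the default caps the conventional 20 at what
#'   the sample size supports.
#' @return A \linkS4class{PLSCV}.
#' @export
selectFactorsLOOCV <- function(X, y,
                               maxFactors = min(20, nrow(X) - 2, ncol(X))) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 samples for LOO factor selection")
  if (maxFactors > min(n - 2, ncol(X)))
    stop("maxFactors exceeds min(n - 2, p)")
  pred <- pls_loocv_cpp(X, y, as.integer(maxFactors))
  rmsecv <- sqrt(colMeans((y - pred)^2))
  new("PLSCV", rmsecv = rmsecv, chosenFactors = which.min(rmsecv))
}

#' Global leave-one-out PLS benchmark predictions
#'
#' For every sample i: fit PLS on all other samples, choosing the factor
#' count by an inner LOO CV, then predict sample i — the global calibration
#' benchmark.  Computed by an exact pair-deleted Krylov formulation of PLS1
#' (each unordered pair of held-out samples shares one fit), which makes the
#' quadratic number of inner fits tractable; results equal the naive
#' fit-per-fold path (see the test suite).
#'
#' When p > n the predictors are first rotated onto an orthonormal basis of
#' their row space (thin SVD), which leaves PLS predictions unchanged.
#'
#' @param X numeric matrix, samples x wavelengths.
#' @param y numeric response.
#' @param maxFactors inner-CV factor cap (default 20, lowered to what the
#'   fold size supports).
#' @return list with \code{pred} (LOO predictions), \code{chosenFactors}
#'   (per-sample inner-CV choice) and \code{rmsecv} (n x maxFactors inner CV
#'   curves).
#' @export
globalLooPredict <- function(X, y, maxFactors = 20) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 4) stop("need at least 4 samples")
  A <- min(maxFactors, n - 3, ncol(X))
  if (ncol(X) > n) {            # rotate to row space; predictions invariant
    sv <- svd(X, nu = 0, nv = min(n, ncol(X)))
    X <- X %*% sv$v
  }
  out <- pls_global_loo_cpp(X, y, as.integer(A))
  out$chosenFactors <- as.integer(out$chosenFactors)
  out$pred <- drop(out$pred)
  out
}

#' Serialise a PLS model to plain text (and back)
#' @param model a \linkS4class{PLSModel}.
#' @param file path.
#' @export
writePLSModel <- function(model, file) {
  con <- file(file, "w"); on.exit(close(con))
  fmt <- function(v) paste(format(v, digits = 17, trim = TRUE),
                           collapse = " ")
  writeLines(c(paste("n_factors", model@nFactors),
               paste("y_center", fmt(model@yCenter)),
               paste("training_ids", paste(model@trainingIds, collapse = " ")),
               paste("x_center", fmt(model@xCenter)),
               paste("x_scale", fmt(model@xScale)),
               "coefficients"), con)
  for (a in seq_len(model@nFactors))
    writeLines(fmt(model@coefficients[, a]), con)
  invisible(file)
}

#' @rdname writePLSModel
#' @export
readPLSModel <- function(file) {
  lines <- readLines(file)
  kv <- function(key) strsplit(sub(paste0("^", key, " "), "",
                                   grep(paste0("^", key, " "), lines,
                                        value = TRUE)[1]), " +")[[1]]
  A <- as.integer(kv("n_factors"))
  start <- which(lines == "coefficients")[1]
  B <- sapply(seq_len(A), function(a)
    as.numeric(strsplit(lines[start + a], " +")[[1]]))
  ids <- grep("^training_ids", lines, value = TRUE)
  ids <- strsplit(sub("^training_ids ?", "", ids), " +")[[1]]
  new("PLSModel", xCenter = as.numeric(kv("x_center")),
      xScale = as.numeric(kv("x_scale")),
      yCenter = as.numeric(kv("y_center")), nFactors = A,
      coefficients = as.matrix(B), trainingIds = ids[nzchar(ids)])
}
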