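## Change-in-mean detection for ordered distance vectors.
##
## Cost convention: a segment y[s..t] costs RSS(s,t)/sigma2, i.e. twice the
## negative Gaussian profile log-likelihood up to constants.  Penalties per
## changepoint: SIC beta = 2*log(n) (one mean + one location parameter),
## MBIC beta = 3*log(n) with an additive log(segment length) term per
## segment (after Zhang & Siegmund).  Ties in the dynamic programme break
## toward the smaller changepoint index.

#' Gaussian mean-change cost of one segment
#'
#' \code{sum((y[s:t] - mean(y[s:t]))^2) / sigma2}.
#'
#' @param y numeric vector.
#' @param s,t 1-based segment bounds, \code{1 <= s <= t <= length(y)}.
#' @param sigma2 positive noise variance.
#' @return the segment cost.
#' @examples
#' segmentCost(c(0, 2), 1, 2, 1)  # 2
#' @export
segmentCost <- function(y, s, t, sigma2) {
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  stopifnot(s >= 1, t >= s, t <= length(y))
  seg <- y[s:t]
  sum((seg - mean(seg))^2) / sigma2
}

#' Estimate the noise variance of a vector with possible mean shifts
#'
#' \describe{
#'   \item{difference_estimator}{\code{var(diff(y)) / 2}; first differences
#'     cancel piecewise-constant means, so the estimate is robust to the
#'     changepoints being sought (the default for sorted distance vectors,
#'     whose scale varies per predictand).}
#'   \item{fixed_one}{1, reproducing common changepoint-package defaults.}
#'   \item{global_mle}{\code{mean((y - mean(y))^2)}.}
#' }
#' A near-zero estimate is floored at machine-epsilon scale with a warning.
#'
#' @param y numeric vector, length >= 2.
#' @param mode estimator choice.
#' @return positive variance estimate.
#' @export
estimateSigma2 <- function(y, mode = c("difference_estimator", "fixed_one",
                                       "global_mle")) {
  mode <- match.arg(mode)
  if (length(y) < 2) stop("need at least 2 values")
  est <- switch(mode,
    difference_estimator = var(diff(y)) / 2,
    fixed_one = 1,
    global_mle = mean((y - mean(y))^2))
  floorVal <- .Machine$double.eps * max(1, mean(y^2))
  if (est <= floorVal) {
    warning("variance estimate ~0; floored at machine-epsilon scale")
    est <- floorVal
  }
  est
}

penaltyBeta <- function(penalty, n) {
  switch(penalty, SIC = 2 * log(n), MBIC = 3 * log(n),
         stop("unknown penalty '", penalty, "'"))
}

## cumulative-sum machinery shared by AMOC/PELT: cost of y[(s+1)..t] given
## 0-based prefix index s, plus the MBIC log-length term when requested
makeCostFun <- function(y, sigma2, mbic) {
  c1 <- c(0, cumsum(y)); c2 <- c(0, cumsum(y^2))
  function(s, t) {  # s: vector of 0-based starts; t scalar end
    len <- t - s
    rss <- (c2[t + 1] - c2[s + 1]) - (c1[t + 1] - c1[s + 1])^2 / len
    rss / sigma2 + if (mbic) log(len) else 0
  }
}

resolveSigma2 <- function(y, sigma2, varianceMode) {
  if (is.null(sigma2)) estimateSigma2(y, varianceMode) else {
    if (sigma2 <= 0) stop("sigma2 must be > 0")
    sigma2
  }
}

#' At-most-one-change detection in the mean
#'
#' Finds the single best split \code{tau} minimising
#' \code{C(1, tau) + C(tau + 1, n)} over admissible splits; the changepoint
#' is reported only when the cost reduction against the no-change model
#' exceeds the penalty.
#'
#' @param y numeric vector (here: sorted Mahalanobis distances).
#' @param penalty "SIC" or "MBIC".
#' @param varianceMode noise variance estimator, see
#'   \code{\link{estimateSigma2}}.
#' @param minSegLen minimum segment length (default 2, so segment means are
#'   well-defined alongside the MBIC log-length term).
#' @param sigma2 optional fixed noise variance overriding varianceMode.
#' @return A \linkS4class{ChangepointFit} with zero or one changepoint.
#' @export
detectAMOC <- function(y, penalty = c("MBIC", "SIC"),
                       varianceMode = c("difference_estimator", "fixed_one",
                                        "global_mle"),
                       minSegLen = 2, sigma2 = NULL) {
  penalty <- match.arg(penalty)
  varianceMode <- match.arg(varianceMode)
  n <- length(y)
  if (n < 2 * minSegLen) stop("vector too short for one change of length-",
                              minSegLen, " segments")
  sigma2 <- resolveSigma2(y, sigma2, varianceMode)
  mbic <- penalty == "MBIC"
  cost <- makeCostFun(y, sigma2, mbic)
  beta <- penaltyBeta(penalty, n)
  taus <- minSegLen:(n - minSegLen)
  altCosts <- vapply(taus, function(tau) cost(0, tau) + cost(tau, n),
                     numeric(1))
  nullCost <- cost(0, n)
  best <- which.min(altCosts)  # first minimum = smallest tau
  if (nullCost - altCosts[best] > beta) {
    new("ChangepointFit", changepoints = as.integer(taus[best]),
        n = as.integer(n), cost = altCosts[best], penaltyValue = beta,
        method = "AMOC", penalty = penalty, sigma2 = sigma2)
  } else {
    new("ChangepointFit", changepoints = integer(0), n = as.integer(n),
        cost = nullCost, penaltyValue = beta, method = "AMOC",
        penalty = penalty, sigma2 = sigma2)
  }
}

#' PELT multiple-changepoint detection in the mean
#'
#' Minimises \code{sum_j cost(segment_j) + m * beta} over all segmentations
#' (m = number of changepoints) by the pruned exact linear time dynamic
#' programme.  The result is identical to exhaustive optimal partitioning:
#' pruning under MBIC keeps a log(n) safety slack because the per-segment
#' log-length term is not superadditive, so no optimal candidate is ever
#' discarded.
#'
#' @inheritParams detectAMOC
#' @return A \linkS4class{ChangepointFit}.
#' @examples
#' y <- rep(c(0, 8, 0), each = 30)
#' detectPELT(y, penalty = "SIC", sigma2 = 1)  # changepoints 30, 60
#' @export
detectPELT <- function(y, penalty = c("MBIC", "SIC"),
                       varianceMode = c("difference_estimator", "fixed_one",
                                        "global_mle"),
                       minSegLen = 2, sigma2 = NULL) {
  penalty <- match.arg(penalty)
  varianceMode <- match.arg(varianceMode)
  n <- length(y)
  if (n < minSegLen) stop("vector shorter than one segment")
  sigma2 <- resolveSigma2(y, sigma2, varianceMode)
  mbic <- penalty == "MBIC"
  cost <- makeCostFun(y, sigma2, mbic)
  beta <- penaltyBeta(penalty, n)
  pruneSlack <- if (mbic) log(n) else 0
  Fv <- c(-beta, rep(Inf, n))   # Fv[s+1] = optimal cost of y[1..s] + m*beta
  prev <- integer(n)            # argmin split (0-based) for each t
  cands <- 0L
  for (t in seq_len(n)) {
    ok <- cands[t - cands >= minSegLen]
    if (length(ok)) {
      cc <- Fv[ok + 1] + cost(ok, t) + beta
      b <- which.min(cc)        # first minimum: smallest split index
      Fv[t + 1] <- cc[b]
      prev[t] <- ok[b]
      keep <- ok[Fv[ok + 1] + cost(ok, t) - (if (mbic) log(t - ok) else 0) <=
                 Fv[t + 1] + pruneSlack]
      cands <- c(keep, cands[t - cands < minSegLen], t)
    } else {
      prev[t] <- 0L
      cands <- c(cands, t)
    }
  }
  tau <- integer(0); t <- n
  while (t > 0) { s <- prev[t]; if (s > 0) tau <- c(s, tau); t <- s }
  m <- length(tau)
  new("ChangepointFit", changepoints = as.integer(tau), n = as.integer(n),
      cost = Fv[n + 1] - m * beta, penaltyValue = beta, method = "PELT",
      penalty = penalty, sigma2 = sigma2)
}

#' Number of segments implied by a changepoint fit
#' @param fit a \linkS4class{ChangepointFit}.
#' @export
nSegments <- function(fit) length(fit@changepoints) + 1L

#' @export
setMethod("show", "ChangepointFit", function(object) {
  cat(sprintf("ChangepointFit (%s/%s): tau=[%s] penalty=%.4g cost=%.6g\n",
              object@method, object@penalty,
              paste(object@changepoints, collapse = ","),
              object@penaltyValue, object@cost))
})
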