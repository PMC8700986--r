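# Independent oracles used across the suite.  These deliberately avoid the
# package's internal machinery: segment costs are naive two-pass sums and
# the segmentation oracle is exhaustive optimal partitioning with no
# pruning.

oracleSegCost <- function(y, s, t, sigma2, mbic) {
  seg <- y[s:t]
  m <- sum(seg) / length(seg)
  acc <- 0
  for (v in seg) acc <- acc + (v - m)^2
  acc / sigma2 + if (mbic) log(length(seg)) else 0
}

# exhaustive O(n^2) dynamic programme over all admissible segmentations;
# ties broken toward the smaller split index (strict improvement required)
oraclePartition <- function(y, beta, sigma2, mbic, minSeg = 2) {
  n <- length(y)
  F <- c(-beta, rep(Inf, n))
  bt <- integer(n)
  for (t in seq_len(n)) {
    if (t < minSeg) next
    for (s in 0:(t - minSeg)) {
      if (!is.finite(F[s + 1])) next
      v <- F[s + 1] + oracleSegCost(y, s + 1, t, sigma2, mbic) + beta
      if (v < F[t + 1]) {
        F[t + 1] <- v
        bt[t] <- s
      }
    }
  }
  tau <- integer(0)
  t <- n
  while (t > 0) {
    s <- bt[t]
    if (s > 0) tau <- c(s, tau)
    t <- s
  }
  tau
}

# exhaustive single-split search with the same decision rule as AMOC
oracleAMOC <- function(y, beta, sigma2, mbic, minSeg = 2) {
  n <- length(y)
  taus <- minSeg:(n - minSeg)
  alt <- sapply(taus, function(tau)
    oracleSegCost(y, 1, tau, sigma2, mbic) +
      oracleSegCost(y, tau + 1, n, sigma2, mbic))
  nullCost <- oracleSegCost(y, 1, n, sigma2, mbic)
  best <- which.min(alt)
  if (nullCost - alt[best] > beta) taus[best] else integer(0)
}

# small dense spectra set with known traits, built directly (no generator)
makeTinySet <- function(n = 12, p = 8, seed = 1, units = "absorbance") {
  set.seed(seed)
  spectra <- matrix(runif(n * p, 0.2, 1.5), n)
  traits <- data.frame(ph = rnorm(n, 6.6, 0.1), rct = rnorm(n, 17, 5))
  SpectraSet(spectra, wavenumbers = seq(1000, by = 50, length.out = p),
             sampleIds = sprintf("s%02d", seq_len(n)),
             animalIds = sprintf("a%02d", seq_len(n)),
             traits = traits, units = units)
}

# 1-D latent dataset whose sorted Mahalanobis distances from the first
# sample equal (up to a common scale) the supplied positive values
makeDistanceSet <- function(values, seed = 1) {
  set.seed(seed)
  lat <- c(0, values)
  p <- 10
  profile <- runif(p, 0.5, 1.5)
  spectra <- outer(lat, profile) + 0.5
  n <- length(lat)
  SpectraSet(spectra, wavenumbers = seq(1000, by = 25, length.out = p),
             sampleIds = sprintf("s%03d", seq_len(n)),
             animalIds = sprintf("a%03d", seq_len(n)),
             traits = data.frame(y = lat + rnorm(n, sd = 0.1)),
             units = "absorbance")
}
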