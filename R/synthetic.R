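## Seeded synthetic mid-infrared spectra with known ground truth.
##
## Generative model: Beer-Lambert-style linear mixing.  Each latent
## chemical component has a smooth absorbance profile (a sum of Gaussian
## peaks on the wavenumber grid); a sample's spectrum is its component
## concentrations times the profiles, plus a smooth per-sample baseline and
## i.i.d. Gaussian noise.  Traits are linear in the concentrations plus
## noise, affinely rescaled to target moments.  Clustered regimes draw
## concentrations from cluster-specific log-normal means and can give each
## cluster its own trait loadings, so locality genuinely helps.

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## retained-style wavenumber grid: the milk MIR region with the
## conventional high-noise windows already absent, so region trimming with
## the default windows is the identity on synthetic data
retainedGrid <- function(nWavelengths) {
  segs <- rbind(c(926, 1577), c(1712, 2988), c(3692, 3820))
  len <- segs[, 2] - segs[, 1]
  counts <- pmax(1, roundHalfAway(nWavelengths * len / sum(len)))
  counts[1] <- counts[1] + (nWavelengths - sum(counts))
  sort(unlist(lapply(seq_len(3), function(i)
    seq(segs[i, 1], segs[i, 2], length.out = counts[i]))))
}

#' Configuration of the synthetic spectra generator
#'
#' Defaults emulate an edited milk mid-infrared dataset: 350 samples by 531
#' retained wavelengths, five latent components, homogeneous (one cluster),
#' and the six technological traits rescaled to realistic milk moments
#' (RCT 17.24/6.61 min, k20 4.95/2.88 min, a30 31.78/15.49 mm,
#' a60 32.22/12.50 mm, CMS 170.20/24.89 nm, pH 6.66/0.09).
#'
#' @param nSamples number of samples.
#' @param nWavelengths retained spectral points (default 531).
#' @param nComponents latent chemical components (default 5).
#' @param nClusters 1 = homogeneous; more for heterogeneous regimes.
#' @param clusterSeparation distance between cluster log-concentration
#'   means, in units of the within-cluster log-concentration SD.
#' @param clusterSpecificTraits when TRUE the first trait's loadings flip
#'   sign between clusters, planting a cluster-driven trait that a single
#'   global linear fit cannot capture.
#' @param peakParams optional list (one per component) of data.frames with
#'   columns centre, width, height; drawn from the seed when NULL.
#' @param traitLoadings traits x components matrix; drawn from the seed
#'   when NULL.
#' @param traitNoiseSD per-trait noise SD in units of the latent trait SD
#'   (default 1: noise and signal of equal size, giving accuracies in the
#'   range typical of milk technological traits).
#' @param traitMoments data.frame with columns mean, sd and one row per
#'   trait; NULL keeps the raw latent scale.
#' @param noiseSD spectral noise SD (absorbance units, default 0.002).
#' @param duplicateAnimalFraction fraction of samples duplicated under a
#'   shared animal id with small perturbations.
#' @param outlierFraction fraction of samples given one >3-SD trait value.
#' @param seed mandatory integer seed; all randomness derives from it.
#' @return validated configuration list (class \code{"SyntheticConfig"}).
#' @export
syntheticConfig <- function(nSamples = 350, nWavelengths = 531,
                            nComponents = 5, nClusters = 1,
                            clusterSeparation = 8,
                            clusterSpecificTraits = FALSE,
                            peakParams = NULL, traitLoadings = NULL,
                            traitNoiseSD = 1,
                            traitMoments = defaultTraitMoments(),
                            noiseSD = 0.002,
                            duplicateAnimalFraction = 0,
                            outlierFraction = 0, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  nTraits <- if (!is.null(traitLoadings)) nrow(traitLoadings)
             else if (!is.null(traitMoments)) nrow(traitMoments)
             else length(TRAIT_NAMES)
  cfg <- list(nSamples = as.integer(nSamples),
              nWavelengths = as.integer(nWavelengths),
              nComponents = as.integer(nComponents),
              nClusters = as.integer(nClusters),
              clusterSeparation = clusterSeparation,
              clusterSpecificTraits = isTRUE(clusterSpecificTraits),
              peakParams = peakParams, traitLoadings = traitLoadings,
              traitNoiseSD = rep_len(traitNoiseSD, nTraits),
              traitMoments = traitMoments, noiseSD = noiseSD,
              duplicateAnimalFraction = duplicateAnimalFraction,
              outlierFraction = outlierFraction,
              seed = as.integer(seed))
  stopifnot(cfg$nSamples >= 4, cfg$nWavelengths >= 4, cfg$nComponents >= 1,
            cfg$nClusters >= 1, cfg$clusterSeparation >= 0,
            all(cfg$traitNoiseSD >= 0), cfg$noiseSD >= 0,
            cfg$duplicateAnimalFraction >= 0,
            cfg$duplicateAnimalFraction < 1,
            cfg$outlierFraction >= 0, cfg$outlierFraction < 1)
  if (!is.null(cfg$traitMoments))
    stopifnot(all(c("mean", "sd") %in% colnames(cfg$traitMoments)),
              all(cfg$traitMoments$sd > 0))
  class(cfg) <- "SyntheticConfig"
  cfg
}

#' Realistic moment targets for the six milk technological traits
#' @return data.frame with rownames rct, k20, a30, a60, cms, ph and columns
#'   mean, sd.
#' @export
defaultTraitMoments <- function() {
  data.frame(mean = c(17.24, 4.95, 31.78, 32.22, 170.20, 6.66),
             sd = c(6.61, 2.88, 15.49, 12.50, 24.89, 0.09),
             row.names = TRAIT_NAMES)
}

gaussianPeaks <- function(wn, peaks) {
  rowSums(sapply(seq_len(nrow(peaks)), function(i)
    peaks$height[i] * exp(-0.5 * ((wn - peaks$centre[i]) /
                                  peaks$width[i])^2)))
}

#' Generate a synthetic SpectraSet
#'
#' Fully reproducible from \code{cfg$seed}.  Ground truth (cluster
#' assignment, latent concentrations, injected outliers and duplicate
#' animals) is stored in \code{metadata(ds)$synthetic}.
#'
#' @param cfg a \code{\link{syntheticConfig}}.
#' @return A \linkS4class{SpectraSet} in absorbance units with a trait
#'   table.
#' @export
generateSpectra <- function(cfg) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  withSeed(cfg$seed, {
    n <- cfg$nSamples; p <- cfg$nWavelengths; K <- cfg$nComponents
    wn <- retainedGrid(p)
    wnScaled <- (wn - min(wn)) / diff(range(wn))

    peaks <- cfg$peakParams
    if (is.null(peaks))
      peaks <- lapply(seq_len(K), function(k)
        data.frame(centre = runif(3, min(wn), max(wn)),
                   width = runif(3, 30, 120),
                   height = runif(3, 0.2, 1)))
    profiles <- t(sapply(peaks, function(pk) gaussianPeaks(wn, pk)))  # K x p

    cluster <- sample.int(cfg$nClusters, n, replace = TRUE)
    sigmaW <- 0.25                       # within-cluster log-conc SD
    mu <- matrix(0, cfg$nClusters, K)
    if (cfg$nClusters > 1) {
      ## clusters placed symmetrically along the leading latent axes, so
      ## the between-cluster direction carries dominant spectral variance
      ## and survives into the leading PCs
      for (g in seq_len(cfg$nClusters)) {
        axis <- (ceiling(g / 2) - 1L) %% K + 1L
        mu[g, axis] <- (-1)^g * cfg$clusterSeparation * sigmaW / 2
      }
    }
    logConc <- mu[cluster, , drop = FALSE] +
      matrix(rnorm(n * K, sd = sigmaW), n)
    conc <- exp(logConc)

    baseline <- outer(rnorm(n, sd = 0.005), rep(1, p)) +
      outer(rnorm(n, sd = 0.005), wnScaled) +
      outer(rnorm(n, sd = 0.002), wnScaled^2)
    spectra <- conc %*% profiles + baseline +
      matrix(rnorm(n * p, sd = cfg$noiseSD), n)

    L <- cfg$traitLoadings
    nTraits <- length(cfg$traitNoiseSD)
    if (is.null(L)) L <- matrix(rnorm(nTraits * K), nTraits)
    traitNames <- if (!is.null(cfg$traitMoments))
      rownames(cfg$traitMoments) else paste0("trait", seq_len(nTraits))
    raw <- conc %*% t(L)                 # n x traits
    if (cfg$clusterSpecificTraits && cfg$nClusters > 1) {
      ## cluster-driven first trait: its loadings flip sign between
      ## clusters and act on centred concentrations, a pure
      ## cluster-by-composition interaction that no single linear
      ## calibration can represent but a within-cluster one can
      flip <- ifelse(cluster == 1, 1, -1)
      raw[, 1] <- flip * drop(sweep(conc, 2, colMeans(conc)) %*% L[1, ])
    }
    traits <- matrix(NA_real_, n, nTraits, dimnames = list(NULL, traitNames))
    for (j in seq_len(nTraits)) {
      s <- sd(raw[, j])
      if (s == 0 && (is.null(cfg$traitMoments) ||
                     cfg$traitMoments$sd[j] > 0))
        stop("latent trait ", j, " has zero variance; moment target infeasible")
      v <- raw[, j] + rnorm(n, sd = cfg$traitNoiseSD[j] * s)
      if (!is.null(cfg$traitMoments))
        v <- (v - mean(v)) / sd(v) * cfg$traitMoments$sd[j] +
          cfg$traitMoments$mean[j]
      traits[, j] <- v
    }

    sampleIds <- sprintf("s%03d", seq_len(n))
    animalIds <- sprintf("a%03d", seq_len(n))

    ## inject trait outliers (one >3-SD value each) into base samples
    nOut <- roundHalfAway(cfg$outlierFraction * n)
    outlierIds <- character(0)
    nDup <- roundHalfAway(cfg$duplicateAnimalFraction * n)
    protected <- if (nDup > 0) seq_len(nDup) else integer(0)
    if (nOut > 0) {
      pool <- setdiff(seq_len(n), protected)
      rows <- sample(pool, nOut)
      cols <- rep_len(seq_len(nTraits), nOut)
      for (idx in seq_len(nOut)) {
        j <- cols[idx]
        m <- mean(traits[, j]); s <- sd(traits[, j])
        traits[rows[idx], j] <- m + sample(c(-1, 1), 1) * 8 * s
      }
      outlierIds <- sampleIds[rows]
    }

    ## duplicate records sharing an animal id, lightly perturbed
    duplicateAnimals <- character(0)
    if (nDup > 0) {
      src <- seq_len(nDup)               # first nDup samples get a twin
      extraSpec <- spectra[src, , drop = FALSE] +
        matrix(rnorm(nDup * p, sd = cfg$noiseSD), nDup)
      extraTraits <- traits[src, , drop = FALSE] *
        (1 + matrix(rnorm(nDup * nTraits, sd = 0.01), nDup))
      spectra <- rbind(spectra, extraSpec)
      traits <- rbind(traits, extraTraits)
      sampleIds <- c(sampleIds, sprintf("s%03dd", src))
      animalIds <- c(animalIds, animalIds[src])
      cluster <- c(cluster, cluster[src])
      duplicateAnimals <- animalIds[src]
    }

    ds <- SpectraSet(spectra, wn, sampleIds, animalIds,
                     as.data.frame(traits), units = "absorbance")
    S4Vectors::metadata(ds)$synthetic <- list(
      cluster = cluster, concentrations = conc, outlierIds = outlierIds,
      duplicateAnimals = duplicateAnimals, seed = cfg$seed)
    ds
  })
}

#' Planted neighbour-structure fixture
#'
#' A dataset with documented ground truth for the changepoint selection
#' rule: \code{nCore} samples form one tight group and \code{nBackground}
#' samples a diffuse cloud centred \code{separation} core-spread units
#' away in a four-dimensional latent space mapped to spectra through
#' smooth component profiles.  For a core predictand the ideal neighbour
#' set is the other \code{nCore - 1} core members.
#'
#' The background is a diffuse shell: each background sample sits at a
#' radius of roughly \code{separation} (10\% radial jitter) from the core
#' centre, in a uniformly random direction of the latent space, while the
#' core spread is \code{separation / 150}.  From a core predictand the
#' sorted distance vector is therefore flat over the core segment and
#' jumps sharply at the group boundary — the structure the selection rule
#' is designed to detect — and the core sits at the centre of the overall
#' PC space while the shell forms its edge.
#'
#' @param nCore tight-group size (>= 21 so the minimum-20 rule can bind).
#' @param nBackground diffuse background size.
#' @param separation radius of the background shell around the core
#'   centre, in latent distance units; must be positive.
#' @param seed integer seed.
#' @return A \linkS4class{SpectraSet} whose
#'   \code{metadata()$planted$coreIds} names the core samples.
#' @export
plantedNeighbourFixture <- function(nCore, nBackground, separation, seed) {
  if (separation <= 0) stop("separation must be > 0")
  if (nCore < 21) stop("nCore must be at least 21")
  withSeed(seed, {
    n <- nCore + nBackground
    dim <- 4
    u <- matrix(rnorm(nBackground * dim), nBackground)
    u <- u / sqrt(rowSums(u^2))
    radius <- separation * (1 + rnorm(nBackground, sd = 0.1))
    latent <- rbind(
      matrix(rnorm(nCore * dim, sd = separation / 150), nCore),
      u * radius)
    p <- 120
    wn <- retainedGrid(p)
    raw <- t(sapply(seq_len(dim), function(k)
      gaussianPeaks(wn, data.frame(centre = runif(3, min(wn), max(wn)),
                                   width = runif(3, 40, 150),
                                   height = runif(3, 0.3, 1)))))
    ## orthonormal rows: the latent -> spectra map is an isometry, so the
    ## planted distance structure carries over exactly
    profiles <- t(qr.Q(qr(t(raw))))
    spectra <- latent %*% profiles + matrix(rnorm(n * p, sd = 1e-4), n)
    ids <- sprintf("s%03d", seq_len(n))
    traits <- data.frame(y = drop(latent %*% rnorm(dim)) + rnorm(n, sd = 0.5))
    ds <- SpectraSet(spectra, wn, ids, sprintf("a%03d", seq_len(n)),
                     traits, units = "absorbance")
    S4Vectors::metadata(ds)$planted <- list(
      coreIds = ids[seq_len(nCore)], latent = latent, seed = seed)
    ds
  })
}
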