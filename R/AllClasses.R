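#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats cor median prcomp quantile rnorm runif rlnorm sd var predict
#' @importFrom utils read.csv write.csv head
#' @importFrom Rcpp evalCpp
#' @useDynLib SpectraCP, .registration = TRUE
NULL

#' The six milk technological traits handled by default
#'
#' Column names used for the trait table: rennet coagulation time (rct, min),
#' curd-firming time (k20, min), curd firmness at 30 and 60 min (a30, a60, mm),
#' casein micelle size (cms, nm) and pH.
#' @export
TRAIT_NAMES <- c("rct", "k20", "a30", "a60", "cms", "ph")

#' SpectraSet: spectra plus per-sample trait annotations
#'
#' A \linkS4class{SummarizedExperiment} with wavelengths as rows and samples
#' as columns.  The single assay \code{"spectra"} holds transmittance or
#' absorbance values (see \code{spectraUnits}); \code{rowData} carries the
#' wavenumber grid (cm-1, strictly increasing) and \code{colData} the animal
#' identifier plus one column per trait.
#'
#' @slot units character, \code{"transmittance"} or \code{"absorbance"}.
#' @export
setClass("SpectraSet",
  contains = "SummarizedExperiment",
  slots = c(units = "character")
)

setValidity("SpectraSet", function(object) {
  msg <- character()
  wn <- SummarizedExperiment::rowData(object)$wavenumber
  if (is.null(wn))
    msg <- c(msg, "rowData must contain a 'wavenumber' column")
  else if (any(diff(wn) <= 0))
    msg <- c(msg, "wavenumbers must be strictly increasing")
  if (!object@units %in% c("transmittance", "absorbance"))
    msg <- c(msg, "units must be 'transmittance' or 'absorbance'")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be present and unique")
  if (is.null(SummarizedExperiment::colData(object)$animal_id))
    msg <- c(msg, "colData must contain 'animal_id'")
  if (length(msg)) msg else TRUE
})

#' Principal-component geometry of a spectral matrix
#'
#' Centering/scaling vectors, orthonormal loadings and the component
#' variances (eigenvalues) that define Mahalanobis distances between
#' PC scores.
#'
#' @slot center per-wavelength mean.
#' @slot scale per-wavelength SD (all ones when unstandardised).
#' @slot loadings n_wavelengths x n_components, orthonormal columns.
#' @slot eigenvalues positive, non-increasing PC score variances.
#' @slot explainedShare share of total variance per component, in [0, 1].
#' @slot standardised logical flag recording the scaling choice.
#' @export
setClass("PCSpace", slots = c(
  center = "numeric",
  scale = "numeric",
  loadings = "matrix",
  eigenvalues = "numeric",
  explainedShare = "numeric",
  standardised = "logical"
))

setValidity("PCSpace", function(object) {
  msg <- character()
  p <- length(object@center)
  if (length(object@scale) != p) msg <- c(msg, "scale/center length mismatch")
  if (nrow(object@loadings) != p) msg <- c(msg, "loadings row count mismatch")
  k <- ncol(object@loadings)
  if (length(object@eigenvalues) != k)
    msg <- c(msg, "one eigenvalue per component required")
  if (any(object@eigenvalues <= 0)) msg <- c(msg, "eigenvalues must be > 0")
  if (is.unsorted(rev(object@eigenvalues)))
    msg <- c(msg, "eigenvalues must be non-increasing")
  if (sum(object@explainedShare) > 1 + 1e-8)
    msg <- c(msg, "explainedShare must sum to <= 1")
  g <- crossprod(object@loadings)
  if (max(abs(g - diag(k))) > 1e-8)
    msg <- c(msg, "loadings must have orthonormal columns")
  if (length(msg)) msg else TRUE
})

#' Changepoints of an ordered vector under a penalised mean-change model
#'
#' @slot changepoints 1-based indices of the last element of each non-final
#'   segment, strictly increasing, all < n.
#' @slot n length of the analysed vector.
#' @slot cost total unpenalised segment cost of the chosen segmentation
#'   (including per-segment MBIC log-length terms when applicable).
#' @slot penaltyValue the per-changepoint penalty beta that was applied.
#' @slot method "AMOC" or "PELT".
#' @slot penalty "SIC" or "MBIC".
#' @slot sigma2 the noise variance used to scale the cost.
#' @export
setClass("ChangepointFit", slots = c(
  changepoints = "integer",
  n = "integer",
  cost = "numeric",
  penaltyValue = "numeric",
  method = "character",
  penalty = "character",
  sigma2 = "numeric"
))

setValidity("ChangepointFit", function(object) {
  tau <- object@changepoints
  if (length(tau) && (any(diff(tau) <= 0) || tau[1] < 1 ||
                      tau[length(tau)] >= object@n))
    return("changepoints must satisfy 1 <= tau_1 < ... < n")
  TRUE
})

#' Single-response partial least squares model
#'
#' Centred (optionally scaled) NIPALS PLS1 fit.  \code{coefficients} holds
#' one column per factor count 1..nFactors so predictions at any smaller
#' number of factors are available without refitting.
#'
#' @slot xCenter,xScale column centring/scaling of the predictors.
#' @slot yCenter response mean.
#' @slot nFactors number of latent factors fitted.
#' @slot coefficients n_wavelengths x nFactors matrix; column a maps
#'   centred/scaled predictors to the centred response using a factors.
#' @slot trainingIds identifiers of the training samples.
#' @export
setClass("PLSModel", slots = c(
  xCenter = "numeric",
  xScale = "numeric",
  yCenter = "numeric",
  nFactors = "integer",
  coefficients = "matrix",
  trainingIds = "character"
))

#' Leave-one-out cross-validation curve for PLS factor selection
#' @slot rmsecv RMSECV indexed by factor count 1..maxFactors.
#' @slot chosenFactors argmin of rmsecv, ties to the smallest count.
#' @export
setClass("PLSCV", slots = c(
  rmsecv = "numeric",
  chosenFactors = "integer"
))

#' Neighbour set feeding one local calibration
#'
#' @slot predictandId the target sample.
#' @slot neighbourIds ordered by ascending distance (changepoint rule) or
#'   descending correlation (LOCAL rule).
#' @slot rule "changepoint", "fixed_k" or "all" (fallback).
#' @slot changepointIndex the changepoint used, or NA.
#' @slot values the distances or correlations aligned to neighbourIds.
#' @export
setClass("NeighbourSelection", slots = c(
  predictandId = "character",
  neighbourIds = "character",
  rule = "character",
  changepointIndex = "integer",
  values = "numeric"
))

setValidity("NeighbourSelection", function(object) {
  if (object@predictandId %in% object@neighbourIds)
    return("predictand must not be among its own neighbours")
  if (length(object@values) != length(object@neighbourIds))
    return("values must align with neighbourIds")
  TRUE
})

#' Benchmark results over traits, approaches and settings
#'
#' @slot metrics data.frame with one row per trait x approach x setting:
#'   rmsev, pearson r, counts, neighbour and factor summaries, and the same
#'   metrics restricted to the edge subsets of PC space.
#' @slot residuals data.frame (sample_id, trait, setting, observed,
#'   predicted, residual, n_neighbours, n_factors).
#' @slot edgeIds list of character vectors: sample ids of each edge subset.
#' @export
setClass("EvaluationReport", slots = c(
  metrics = "data.frame",
  residuals = "data.frame",
  edgeIds = "list"
))
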