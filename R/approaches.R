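#' Configuration of a prediction approach
#'
#' Bundles every setting that defines one prediction strategy:
#' \describe{
#'   \item{global}{PLS on all other samples, LOO-CV factor selection.}
#'   \item{local_shenk}{the LOCAL strategy: \code{shenkK} neighbours ranked
#'     by Pearson correlation with the predictand spectrum, a fixed
#'     \code{shenkFactors} PLS factors.}
#'   \item{local_changepoint}{neighbour count chosen per predictand by
#'     changepoint analysis of sorted Mahalanobis distances in PC space,
#'     LOO-CV factor selection.}
#' }
#'
#' @param approach one of \code{"global"}, \code{"local_shenk"},
#'   \code{"local_changepoint"}.
#' @param standardise standardise spectra before the PC fit used for
#'   neighbour geometry.
#' @param nPcs PC-space dimension (default 4).
#' @param penalty changepoint penalty, \code{"MBIC"} or \code{"SIC"}.
#' @param minNeighbours smallest admissible neighbour count (default 20, so
#'   LOO factor selection stays meaningful on the neighbour set).
#' @param shenkK,shenkFactors LOCAL neighbour and factor counts
#'   (conventional grids: 25/50/100 and 5/10/20).
#' @param maxFactors cap on CV-selected factor counts (default 20).
#' @param pcFitScope \code{"full_dataset"} fits one PC space on the whole
#'   edited dataset; \code{"exclude_predictand"} refits without the
#'   predictand for strictly leakage-free geometry.
#' @param cpMethod changepoint search, \code{"PELT"} (default) or
#'   \code{"AMOC"}.
#' @param varianceMode noise-variance estimator for the changepoint cost.
#' @return a named list of validated settings (class
#'   \code{"ApproachConfig"}).
#' @export
approachConfig <- function(approach = c("global", "local_shenk",
                                        "local_changepoint"),
                           standardise = TRUE, nPcs = 4,
                           penalty = c("MBIC", "SIC"), minNeighbours = 20,
                           shenkK = 25, shenkFactors = 5, maxFactors = 20,
                           pcFitScope = c("full_dataset",
                                          "exclude_predictand"),
                           cpMethod = c("PELT", "AMOC"),
                           varianceMode = c("difference_estimator",
                                            "fixed_one", "global_mle")) {
  cfg <- list(approach = match.arg(approach),
              standardise = isTRUE(standardise),
              nPcs = as.integer(nPcs),
              penalty = match.arg(penalty),
              minNeighbours = as.integer(minNeighbours),
              shenkK = as.integer(shenkK),
              shenkFactors = as.integer(shenkFactors),
              maxFactors = as.integer(maxFactors),
              pcFitScope = match.arg(pcFitScope),
              cpMethod = match.arg(cpMethod),
              varianceMode = match.arg(varianceMode))
  stopifnot(cfg$nPcs >= 1, cfg$minNeighbours >= 2, cfg$shenkK >= 2,
            cfg$shenkFactors >= 1, cfg$maxFactors >= 1)
  class(cfg) <- "ApproachConfig"
  cfg
}

#' Short label describing an approach configuration
#' @param cfg an ApproachConfig.
#' @export
configLabel <- function(cfg) {
  switch(cfg$approach,
    global = "global",
    local_shenk = sprintf("local_k%d_f%d", cfg$shenkK, cfg$shenkFactors),
    local_changepoint = sprintf("cp_%s_%s", cfg$penalty,
                                if (cfg$standardise) "std" else "unstd"))
}

## PC geometry for neighbour selection under the configured scope.
## full_dataset: one space for all predictands (the usual global geometry);
## exclude_predictand: refit per predictand for leakage-free benchmarking.
neighbourGeometry <- function(ds, cfg) {
  X <- spectraMatrix(ds)
  if (cfg$pcFitScope == "full_dataset") {
    space <- fitPCSpace(X, standardise = cfg$standardise,
                        nComponents = cfg$nPcs)
    scores <- projectScores(space, X)
    function(i) list(space = space, scores = scores)
  } else {
    function(i) {
      space <- fitPCSpace(X[-i, , drop = FALSE],
                          standardise = cfg$standardise,
                          nComponents = cfg$nPcs)
      list(space = space, scores = projectScores(space, X))
    }
  }
}

#' Select neighbours for one predictand by changepoint analysis
#'
#' Computes Mahalanobis distances in PC space from the predictand to every
#' other sample, sorts them in increasing order, and runs a changepoint
#' search on the sorted vector.  The neighbour count is the smallest
#' changepoint index of at least \code{minNeighbours}; when no changepoint
#' qualifies the selection falls back to all candidates (rule \code{"all"},
#' with a warning) — a flat distance profile signals no local structure.
#'
#' @param ds an edited \linkS4class{SpectraSet}.
#' @param predictandId sample id of the target spectrum.
#' @param cfg an \code{\link{approachConfig}}.
#' @return A \linkS4class{NeighbourSelection}.
#' @export
selectNeighboursChangepoint <- function(ds, predictandId,
                                        cfg = approachConfig("local_changepoint")) {
  ids <- sampleIds(ds)
  i <- match(predictandId, ids)
  if (is.na(i)) stop("unknown sample id '", predictandId, "'")
  n <- length(ids)
  if (n - 1 < cfg$minNeighbours)
    stop("fewer candidates than minNeighbours")
  geom <- neighbourGeometry(ds, cfg)(i)
  d <- mahalanobisToAll(geom$space, geom$scores, i)[-i]
  candidates <- ids[-i]
  ord <- order(d, seq_along(d))          # ties by sample-id order
  dSorted <- d[ord]
  fit <- if (cfg$cpMethod == "PELT")
    detectPELT(dSorted, penalty = cfg$penalty,
               varianceMode = cfg$varianceMode)
  else detectAMOC(dSorted, penalty = cfg$penalty,
                  varianceMode = cfg$varianceMode)
  tau <- fit@changepoints[fit@changepoints >= cfg$minNeighbours]
  if (length(tau)) {
    k <- tau[1]
    rule <- "changepoint"
    cpUsed <- as.integer(k)
  } else {
    k <- length(candidates)
    rule <- "all"
    cpUsed <- NA_integer_
    warning("no changepoint selected >= ", cfg$minNeighbours,
            " neighbours for '", predictandId, "'; using all candidates")
  }
  new("NeighbourSelection", predictandId = predictandId,
      neighbourIds = candidates[ord][seq_len(k)], rule = rule,
      changepointIndex = cpUsed, values = dSorted[seq_len(k)])
}

#' Select neighbours for one predictand by spectral correlation (LOCAL)
#'
#' Ranks candidates by the Pearson correlation between the predictand's
#' absorbance vector and each candidate's, over the retained wavelengths,
#' and keeps the top \code{k}.  Zero-variance candidate spectra have no
#' defined correlation and are excluded with a warning.
#'
#' @param ds an edited \linkS4class{SpectraSet}.
#' @param predictandId sample id of the target spectrum.
#' @param k number of neighbours to keep (must be < n - 1).
#' @return A \linkS4class{NeighbourSelection} with rule \code{"fixed_k"}.
#' @export
selectNeighboursShenk <- function(ds, predictandId, k = 25) {
  ids <- sampleIds(ds)
  i <- match(predictandId, ids)
  if (is.na(i)) stop("unknown sample id '", predictandId, "'")
  if (k >= length(ids) - 1) stop("k must be smaller than the candidate count")
  X <- spectraMatrix(ds)
  x0 <- X[i, ]
  if (sd(x0) == 0) stop("predictand spectrum has zero variance")
  cand <- setdiff(seq_along(ids), i)
  sds <- apply(X[cand, , drop = FALSE], 1, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance candidate spectrum(s) excluded")
    cand <- cand[sds > 0]
  }
  r <- as.numeric(cor(x0, t(X[cand, , drop = FALSE])))
  ord <- order(-r, seq_along(r))          # ties by sample-id order
  top <- ord[seq_len(k)]
  new("NeighbourSelection", predictandId = predictandId,
      neighbourIds = ids[cand][top], rule = "fixed_k",
      changepointIndex = NA_integer_, values = r[top])
}

#' @export
setMethod("show", "NeighbourSelection", function(object) {
  cat(sprintf("NeighbourSelection (%s): %d neighbours for '%s'%s\n",
              object@rule, length(object@neighbourIds), object@predictandId,
              if (!is.na(object@changepointIndex))
                sprintf(" (changepoint at %d)", object@changepointIndex)
              else ""))
})

traitVector <- function(ds, trait) {
  tt <- traitTable(ds)
  if (!trait %in% colnames(tt)) stop("unknown trait '", trait, "'")
  v <- tt[[trait]]
  names(v) <- sampleIds(ds)
  v
}

#' Predict one trait for one predictand under a configured approach
#'
#' The model that produces the prediction is always fitted without the
#' predictand: global uses all other samples with LOO-CV factor selection;
#' local_shenk fits the fixed-k correlation neighbours with the fixed factor
#' count; local_changepoint fits the changepoint-selected neighbours with
#' LOO-CV factor selection capped at \code{min(maxFactors, k - 2)}.
#'
#' @param ds an edited \linkS4class{SpectraSet}.
#' @param predictandId sample id of the target.
#' @param trait trait column name.
#' @param cfg an \code{\link{approachConfig}}.
#' @param details return a list with the prediction plus the neighbour set,
#'   factor count and training ids (used by the leakage audit) instead of a
#'   bare number.
#' @return numeric prediction, or a list when \code{details = TRUE}.
#' @export
predictTrait <- function(ds, predictandId, trait,
                         cfg = approachConfig("global"), details = FALSE) {
  ids <- sampleIds(ds)
  i <- match(predictandId, ids)
  if (is.na(i)) stop("unknown sample id '", predictandId, "'")
  X <- spectraMatrix(ds)
  y <- traitVector(ds, trait)
  sel <- switch(cfg$approach,
    global = NULL,
    local_shenk = selectNeighboursShenk(ds, predictandId, cfg$shenkK),
    local_changepoint = selectNeighboursChangepoint(ds, predictandId, cfg))
  trainIds <- if (is.null(sel)) ids[-i] else sel@neighbourIds
  if (anyNA(y[trainIds])) stop("trait '", trait,
                               "' missing for some training samples")
  if (length(trainIds) < 3)
    stop("neighbour set too small for cross-validation (",
         length(trainIds), " < 3)")
  Xt <- X[trainIds, , drop = FALSE]
  yt <- y[trainIds]
  if (cfg$approach == "local_shenk") {
    nf <- min(cfg$shenkFactors, length(trainIds) - 1, ncol(Xt))
    model <- fitPLS(Xt, yt, nf, trainingIds = trainIds)
  } else {
    cap <- min(cfg$maxFactors, length(trainIds) - 2, ncol(Xt))
    cv <- selectFactorsLOOCV(Xt, yt, maxFactors = cap)
    model <- fitPLS(Xt, yt, cv@chosenFactors, trainingIds = trainIds)
  }
  pred <- predict(model, X[i, ])
  if (!details) return(pred)
  list(prediction = pred, trainingIds = trainIds,
       nNeighbours = length(trainIds), nFactors = model@nFactors,
       rule = if (is.null(sel)) "global" else sel@rule,
       selection = sel)
}
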