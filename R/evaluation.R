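#' Root mean square error of validation predictions
#' @param yTrue,yPred numeric vectors of equal length.
#' @return sqrt(mean((yTrue - yPred)^2)).
#' @export
rmsev <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  if (!length(yTrue)) stop("empty vectors")
  sqrt(mean((yTrue - yPred)^2))
}

#' Pearson correlation between observed and predicted values
#'
#' Returns NA with a warning when either vector has zero variance (the
#' correlation is then undefined).
#' @param yTrue,yPred numeric vectors of equal length.
#' @export
pearsonR <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  if (sd(yTrue) == 0 || sd(yPred) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  cor(yTrue, yPred)
}

## round-half-away-from-zero (base round() is banker's rounding)
roundHalfAway <- function(x) floor(x + 0.5)

#' Samples at the edge of PC space
#'
#' The \code{round(fraction * n)} samples with the greatest Mahalanobis
#' distance from the centre of the PC space (the zero score vector).
#' Fractional subset sizes use round-half-away-from-zero; ties at the cut
#' break by sample-id order.
#'
#' @param ds a \linkS4class{SpectraSet}.
#' @param space a \linkS4class{PCSpace}; by convention the standardised
#'   4-component space of the full dataset.
#' @param fraction subset share, strictly between 0 and 1.
#' @return character vector of sample ids, most distant first.
#' @export
edgeSubset <- function(ds, space, fraction = 0.05) {
  stopifnot(fraction > 0, fraction < 1)
  n <- ncol(ds)
  size <- roundHalfAway(fraction * n)
  if (size < 2) stop("edge subset would have fewer than 2 samples")
  d <- mahalanobisFromCentre(space, projectScores(space, ds))
  sampleIds(ds)[order(-d, seq_len(n))[seq_len(size)]]
}

#' The conventional benchmark grid of approach settings
#'
#' One global configuration, the nine LOCAL combinations (25/50/100
#' neighbours x 5/10/20 factors) and the four changepoint configurations
#' ({SIC, MBIC} x {standardised, unstandardised}) — fourteen settings in
#' total.
#' @param maxFactors factor cap passed to the CV-based approaches.
#' @param minNeighbours minimum changepoint neighbour count.
#' @return list of \code{\link{approachConfig}} objects.
#' @export
defaultConfigGrid <- function(maxFactors = 20, minNeighbours = 20) {
  grid <- list(approachConfig("global", maxFactors = maxFactors))
  for (k in c(25, 50, 100))
    for (f in c(5, 10, 20))
      grid <- c(grid, list(approachConfig("local_shenk", shenkK = k,
                                          shenkFactors = f)))
  for (pen in c("MBIC", "SIC"))
    for (std in c(TRUE, FALSE))
      grid <- c(grid, list(approachConfig("local_changepoint",
                                          penalty = pen, standardise = std,
                                          maxFactors = maxFactors,
                                          minNeighbours = minNeighbours)))
  grid
}

## all neighbour selections for one local config (trait-independent)
allSelections <- function(ds, cfg) {
  ids <- sampleIds(ds)
  if (cfg$approach == "local_shenk")
    lapply(ids, function(id) selectNeighboursShenk(ds, id, cfg$shenkK))
  else
    lapply(ids, function(id)
      suppressWarnings(selectNeighboursChangepoint(ds, id, cfg)))
}

#' Leave-one-out benchmark of prediction approaches
#'
#' For every sample, trait and configuration: one prediction from a model
#' that never saw that sample.  Aggregates RMSEV, Pearson r, neighbour and
#' factor count summaries, and the same metrics restricted to the
#' edge-of-PC-space subsets.  Fully deterministic given the dataset and
#' configurations.
#'
#' Neighbour selection is trait-independent, so each local configuration
#' selects once and reuses the sets across traits.  The global approach
#' runs through the pair-deleted fast path (see
#' \code{\link{globalLooPredict}}).
#'
#' @param ds an edited \linkS4class{SpectraSet} with a complete trait table.
#' @param configs list of \code{\link{approachConfig}} objects.
#' @param traits trait columns to evaluate (default: all).
#' @param edgeFractions edge subset shares (default 5\% and 10\%).
#' @return An \linkS4class{EvaluationReport}.
#' @export
runBenchmark <- function(ds, configs = defaultConfigGrid(),
                         traits = colnames(traitTable(ds)),
                         edgeFractions = c(0.05, 0.10)) {
  n <- ncol(ds)
  if (n < 2) stop("benchmark needs at least 2 samples")
  ids <- sampleIds(ds)
  X <- spectraMatrix(ds)
  if (anyNA(as.matrix(traitTable(ds)[, traits, drop = FALSE])))
    stop("trait table must be complete; run editSpectra() first")

  edgeSpace <- fitPCSpace(X, standardise = TRUE, nComponents = 4)
  edgeIds <- lapply(edgeFractions, function(f) edgeSubset(ds, edgeSpace, f))
  names(edgeIds) <- sprintf("edge%g", edgeFractions * 100)

  metrics <- list(); resid <- list()
  for (cfg in configs) {
    lab <- configLabel(cfg)
    sels <- if (cfg$approach != "global") allSelections(ds, cfg) else NULL
    for (trait in traits) {
      y <- traitVector(ds, trait)
      pred <- numeric(n)
      nNb <- integer(n); nFac <- integer(n)
      if (cfg$approach == "global") {
        g <- globalLooPredict(X, y, maxFactors = cfg$maxFactors)
        pred <- g$pred
        nFac <- g$chosenFactors
        nNb <- rep(n - 1L, n)
      } else {
        for (i in seq_len(n)) {
          sel <- sels[[i]]
          tr <- match(sel@neighbourIds, ids)
          Xt <- X[tr, , drop = FALSE]; yt <- y[tr]
          if (cfg$approach == "local_shenk") {
            nf <- min(cfg$shenkFactors, length(tr) - 1, ncol(Xt))
          } else {
            cap <- min(cfg$maxFactors, length(tr) - 2, ncol(Xt))
            cv <- selectFactorsLOOCV(Xt, yt, maxFactors = cap)
            nf <- cv@chosenFactors
          }
          model <- fitPLS(Xt, yt, nf)
          pred[i] <- predict(model, X[i, ])
          nNb[i] <- length(tr); nFac[i] <- nf
        }
      }
      row <- data.frame(trait = trait, approach = cfg$approach,
                        setting = lab, n = n,
                        rmsev = rmsev(y, pred),
                        r = suppressWarnings(pearsonR(y, pred)),
                        neighbours_mean = mean(nNb),
                        neighbours_min = min(nNb),
                        neighbours_max = max(nNb),
                        factors_median = median(nFac),
                        factors_min = min(nFac),
                        factors_max = max(nFac),
                        stringsAsFactors = FALSE)
      for (e in names(edgeIds)) {
        sub <- match(edgeIds[[e]], ids)
        row[[paste0(e, "_rmsev")]] <- rmsev(y[sub], pred[sub])
        row[[paste0(e, "_r")]] <- suppressWarnings(pearsonR(y[sub],
                                                            pred[sub]))
      }
      metrics[[length(metrics) + 1]] <- row
      resid[[length(resid) + 1]] <- data.frame(
        sample_id = ids, trait = trait, setting = lab, observed = y,
        predicted = pred, residual = y - pred, n_neighbours = nNb,
        n_factors = nFac, stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  new("EvaluationReport", metrics = do.call(rbind, metrics),
      residuals = do.call(rbind, resid), edgeIds = edgeIds)
}

#' @export
setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport:", nrow(object@metrics), "trait x setting rows,",
      length(unique(object@metrics$trait)), "traits\n")
  print(head(object@metrics[, c("trait", "setting", "rmsev", "r")], 12))
})

#' Write an evaluation report to delimited text
#'
#' One CSV row per trait x approach x setting, and optionally the full
#' residual table for plotting.
#' @param report an \linkS4class{EvaluationReport}.
#' @param metricsFile path for the metrics CSV.
#' @param residualsFile optional path for the residual table.
#' @export
writeReportCSV <- function(report, metricsFile, residualsFile = NULL) {
  fmtNum <- function(df) {
    for (nm in colnames(df)) if (is.numeric(df[[nm]]))
      df[[nm]] <- format(df[[nm]], digits = 12, trim = TRUE,
                         scientific = FALSE)
    df
  }
  write.csv(fmtNum(report@metrics), metricsFile, row.names = FALSE,
            quote = FALSE)
  if (!is.null(residualsFile))
    write.csv(fmtNum(report@residuals), residualsFile, row.names = FALSE,
              quote = FALSE)
  invisible(metricsFile)
}
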