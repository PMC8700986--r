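#' Default high-noise discard windows for milk mid-infrared spectra
#'
#' Water-associated high-noise regions conventionally removed before
#' calibration: 1580-1710 cm-1, 2990-3690 cm-1 and everything above
#' 3822 cm-1.  A window is a numeric length-2 vector \code{c(lo, hi)},
#' closed at both ends; when \code{hi} is \code{Inf} the lower end is open
#' (strictly greater than \code{lo}).
#' @return list of numeric length-2 vectors.
#' @export
defaultDiscardWindows <- function() {
  list(c(1580, 1710), c(2990, 3690), c(3822, Inf))
}

windowMembership <- function(wn, window) {
  if (is.infinite(window[2])) wn > window[1]
  else wn >= window[1] & wn <= window[2]
}

#' Transmittance to absorbance transform
#'
#' A = log10(1/T), elementwise.  All transmittance values must be strictly
#' positive; offending entries are reported by sample and wavenumber.
#'
#' @param x a numeric matrix (samples x wavelengths) or a
#'   \linkS4class{SpectraSet} in transmittance units.
#' @return object of the same kind in absorbance units.
#' @examples
#' toAbsorbance(matrix(c(1, 0.1, 0.01), 1))  # 0, 1, 2
#' @export
toAbsorbance <- function(x) {
  if (is(x, "SpectraSet")) {
    if (spectraUnits(x) == "absorbance")
      stop("spectra are already in absorbance units")
    m <- spectraMatrix(x)
    bad <- which(m <= 0, arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf(
        "non-positive transmittance: sample '%s' at %g cm-1 (value %g)%s",
        sampleIds(x)[bad[1, 1]], wavenumbers(x)[bad[1, 2]],
        m[bad[1, 1], bad[1, 2]],
        if (nrow(bad) > 1) sprintf(" and %d more", nrow(bad) - 1) else ""))
    }
    out <- x
    SummarizedExperiment::assay(out, "spectra") <- t(log10(1 / m))
    out@units <- "absorbance"
    return(out)
  }
  m <- as.matrix(x)
  bad <- which(m <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-positive transmittance at row %d, column %d (value %g)",
                 bad[1, 1], bad[1, 2], m[bad[1, 1], bad[1, 2]]))
  log10(1 / m)
}

#' Remove spectral regions inside discard windows
#'
#' Drops every wavelength whose wavenumber falls inside any window (see
#' \code{\link{defaultDiscardWindows}} for the interval conventions);
#' column order is preserved and removal counts are logged per window.
#'
#' @param x a \linkS4class{SpectraSet}.
#' @param windows list of discard windows.
#' @return the trimmed SpectraSet.
#' @export
trimRegions <- function(x, windows = defaultDiscardWindows()) {
  wn <- wavenumbers(x)
  drop <- rep(FALSE, length(wn))
  for (w in windows) {
    inside <- windowMembership(wn, w)
    message(sprintf("trimRegions: window [%s, %s] removes %d wavelengths",
                    format(w[1]), format(w[2]), sum(inside)))
    drop <- drop | inside
  }
  if (all(drop)) stop("trimRegions would remove every wavelength")
  x[!drop, ]
}

#' Remove per-trait outliers and incomplete samples
#'
#' For each trait, samples whose value lies more than \code{sdThreshold}
#' standard deviations from the trait mean are dropped; mean and SD are
#' computed once on the pre-filter values (sample SD, n-1 denominator).
#' Samples missing any trait are then dropped, so the result is complete.
#' A zero-variance trait yields no removals.
#'
#' @param x a \linkS4class{SpectraSet} with a trait table.
#' @param sdThreshold positive number of SDs (default 3).
#' @return the filtered SpectraSet.
#' @export
removeTraitOutliers <- function(x, sdThreshold = 3) {
  stopifnot(sdThreshold > 0)
  tt <- traitTable(x)
  if (!ncol(tt)) stop("no traits to filter on")
  keep <- rep(TRUE, ncol(x))
  for (nm in colnames(tt)) {
    v <- tt[[nm]]
    ok <- !is.na(v)
    if (sum(ok) < 2) stop("trait '", nm, "' has fewer than 2 values")
    m <- mean(v[ok]); s <- sd(v[ok])
    out <- ok & s > 0 & abs(v - m) > sdThreshold * s
    message(sprintf("removeTraitOutliers: %s drops %d sample(s)", nm,
                    sum(out, na.rm = TRUE)))
    keep <- keep & !(out %in% TRUE)
  }
  complete <- !apply(is.na(as.matrix(tt)), 1, any)
  message(sprintf("removeTraitOutliers: %d incomplete sample(s) dropped",
                  sum(keep & !complete)))
  keep <- keep & complete
  if (!any(keep)) stop("all samples removed by trait filtering")
  x[, keep]
}

#' Keep one record per animal, the most PC-space-extreme
#'
#' Where an animal has multiple records, only the record with the greatest
#' Mahalanobis distance between its principal-component scores and the
#' average scores of the whole dataset is retained, maximising retained
#' variability.  Ties go to the first occurrence.
#'
#' @param x a \linkS4class{SpectraSet}.
#' @param nPcs number of principal components for the distance geometry.
#' @param standardise centre-and-scale the spectra before the PC fit.
#' @return the deduplicated SpectraSet.
#' @export
deduplicateAnimals <- function(x, nPcs = 4, standardise = TRUE) {
  an <- animalIds(x)
  if (!anyDuplicated(an)) return(x)
  if (ncol(x) < nPcs + 1)
    stop("need more samples than PCs to deduplicate")
  space <- fitPCSpace(spectraMatrix(x), standardise = standardise,
                      nComponents = nPcs)
  sc <- projectScores(space, spectraMatrix(x))
  d <- mahalanobisFromCentre(space, sc)
  keep <- rep(TRUE, ncol(x))
  for (a in unique(an[duplicated(an)])) {
    idx <- which(an == a)
    keep[idx] <- FALSE
    keep[idx[which.max(d[idx])]] <- TRUE  # which.max: ties to first
  }
  message(sprintf("deduplicateAnimals: %d duplicate record(s) removed",
                  sum(!keep)))
  x[, keep]
}

#' Full spectral editing pipeline
#'
#' Applies the editing steps in a fixed order: animal deduplication,
#' high-noise region trimming, transmittance-to-absorbance transform (when
#' the input is in transmittance), then trait outlier removal and
#' completeness filtering.  Row/column counts are logged after each stage;
#' re-running the pipeline on its own output is a no-op.
#'
#' @param x a \linkS4class{SpectraSet}.
#' @param windows discard windows for \code{\link{trimRegions}}.
#' @param sdThreshold SD multiple for \code{\link{removeTraitOutliers}}.
#' @param deduplicate apply the animal deduplication step.
#' @param nPcsDedup,standardiseDedup PC geometry for deduplication.
#' @return the edited SpectraSet, in absorbance units, with unique animals
#'   and a complete trait table.
#' @export
editSpectra <- function(x, windows = defaultDiscardWindows(),
                        sdThreshold = 3, deduplicate = TRUE,
                        nPcsDedup = 4, standardiseDedup = TRUE) {
  logdim <- function(stage, d)
    message(sprintf("editSpectra [%s]: %d samples x %d wavelengths",
                    stage, ncol(d), nrow(d)))
  logdim("input", x)
  if (deduplicate) {
    x <- deduplicateAnimals(x, nPcs = nPcsDedup,
                            standardise = standardiseDedup)
    logdim("dedup", x)
  }
  x <- trimRegions(x, windows)
  logdim("trim", x)
  if (spectraUnits(x) == "transmittance") {
    x <- toAbsorbance(x)
    logdim("absorbance", x)
  }
  x <- removeTraitOutliers(x, sdThreshold)
  logdim("outliers", x)
  x
}
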