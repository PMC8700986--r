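#' Fit the principal-component geometry of a spectral matrix
#'
#' Centres (and optionally scales) the spectra, then takes the leading
#' eigenvectors of the covariance.  The returned \linkS4class{PCSpace}
#' carries everything needed to project new spectra and to compute
#' Mahalanobis distances between score vectors: PC scores are uncorrelated,
#' so their covariance is the diagonal matrix of eigenvalues.
#'
#' Loading signs follow a deterministic convention: the largest-magnitude
#' entry of each column is positive.  Zero-variance columns under
#' standardisation get scale 1 with a warning.  Four components are the
#' default: for milk MIR spectra they carry essentially all spectral
#' variance, and adding more does not change neighbour sets.
#'
#' @param spectra numeric matrix, samples x wavelengths, or a
#'   \linkS4class{SpectraSet}.
#' @param standardise centre and scale (TRUE) or centre only (FALSE).
#' @param nComponents number of components to retain (default 4).
#' @return A \linkS4class{PCSpace}.
#' @export
fitPCSpace <- function(spectra, standardise = TRUE, nComponents = 4) {
  if (is(spectra, "SpectraSet")) spectra <- spectraMatrix(spectra)
  X <- as.matrix(spectra)
  n <- nrow(X); p <- ncol(X)
  if (nComponents > min(n - 1, p))
    stop(sprintf("nComponents (%d) exceeds min(n_samples-1, n_wavelengths) = %d",
                 nComponents, min(n - 1, p)))
  ctr <- colMeans(X)
  if (standardise) {
    scl <- apply(X, 2, sd)
    if (any(scl == 0)) {
      warning(sum(scl == 0), " zero-variance column(s); scale set to 1")
      scl[scl == 0] <- 1
    }
  } else scl <- rep(1, p)
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  sv <- svd(Z, nu = 0, nv = min(n - 1, p))
  ev <- sv$d^2 / (n - 1)
  total <- sum(ev)
  if (ev[nComponents] <= total * 1e-12)
    stop(sprintf("matrix rank is below the %d requested components",
                 nComponents))
  load <- sv$v[, seq_len(nComponents), drop = FALSE]
  for (k in seq_len(nComponents)) {           # deterministic sign
    j <- which.max(abs(load[, k]))
    if (load[j, k] < 0) load[, k] <- -load[, k]
  }
  new("PCSpace", center = ctr, scale = scl, loadings = load,
      eigenvalues = ev[seq_len(nComponents)],
      explainedShare = ev[seq_len(nComponents)] / total,
      standardised = standardise)
}

#' Project spectra onto a fitted PC space
#' @param space a \linkS4class{PCSpace}.
#' @param x numeric matrix (samples x wavelengths), single spectrum vector,
#'   or \linkS4class{SpectraSet}; wavelength count must match the space.
#' @return score matrix, samples x components.
#' @rdname projectScores
#' @export
setMethod("projectScores", "PCSpace", function(space, x) {
  if (is(x, "SpectraSet")) x <- spectraMatrix(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(space@center))
    stop("wavelength count does not match the PC space")
  sweep(sweep(x, 2, space@center), 2, space@scale, "/") %*% space@loadings
})

#' Mahalanobis distance between two PC score vectors
#'
#' sqrt(sum_k (a_k - b_k)^2 / lambda_k): the Mahalanobis distance under the
#' diagonal score covariance, lambda_k being the component variances.
#'
#' @param space a \linkS4class{PCSpace}.
#' @param a,b score vectors of length nComponents.
#' @return non-negative distance.
#' @export
mahalanobisPC <- function(space, a, b) {
  k <- ncol(space@loadings)
  if (length(a) != k || length(b) != k)
    stop("score vectors must have length ", k)
  sqrt(sum((a - b)^2 / space@eigenvalues))
}

#' Mahalanobis distances from each score row to the space centre
#' @param space a \linkS4class{PCSpace}.
#' @param scores score matrix (samples x components).
#' @return numeric vector of distances to the zero score vector.
#' @export
mahalanobisFromCentre <- function(space, scores) {
  scores <- as.matrix(scores)
  sqrt(colSums(t(scores)^2 / space@eigenvalues))
}

#' Mahalanobis distances from one sample's scores to many
#' @param space a \linkS4class{PCSpace}.
#' @param scores score matrix (samples x components).
#' @param idx row index of the reference sample.
#' @return distances from row idx to every row (0 at idx itself).
#' @export
mahalanobisToAll <- function(space, scores, idx) {
  scores <- as.matrix(scores)
  diff <- sweep(scores, 2, scores[idx, ])
  sqrt(colSums(t(diff)^2 / space@eigenvalues))
}

#' @export
setMethod("show", "PCSpace", function(object) {
  cat("PCSpace:", ncol(object@loadings), "components over",
      length(object@center), "wavelengths (",
      if (object@standardised) "standardised" else "unstandardised", ")\n")
  cat("  explained share:",
      paste(sprintf("%.3f", object@explainedShare), collapse = " "), "\n")
})

#' Serialise a PCSpace to a plain-text file (and back)
#'
#' Key-value header (standardised flag, dimensions, eigenvalues) followed by
#' whitespace-delimited center, scale and loading values; full precision.
#' @param space a \linkS4class{PCSpace}.
#' @param file path.
#' @return \code{readPCSpace} returns the reconstructed object.
#' @export
writePCSpace <- function(space, file) {
  con <- file(file, "w"); on.exit(close(con))
  fmt <- function(v) paste(format(v, digits = 17, trim = TRUE),
                           collapse = " ")
  writeLines(c(
    paste("standardised", space@standardised),
    paste("n_wavelengths", length(space@center)),
    paste("n_components", ncol(space@loadings)),
    paste("eigenvalues", fmt(space@eigenvalues)),
    paste("explained_share", fmt(space@explainedShare)),
    paste("center", fmt(space@center)),
    paste("scale", fmt(space@scale)),
    "loadings"), con)
  for (k in seq_len(ncol(space@loadings)))
    writeLines(fmt(space@loadings[, k]), con)
  invisible(file)
}

#' @rdname writePCSpace
#' @export
readPCSpace <- function(file) {
  lines <- readLines(file)
  kv <- function(key) strsplit(sub(paste0("^", key, " "), "",
                                   grep(paste0("^", key, " "), lines,
                                        value = TRUE)[1]), " +")[[1]]
  k <- as.integer(kv("n_components"))
  loadStart <- which(lines == "loadings")[1]
  load <- sapply(seq_len(k), function(i)
    as.numeric(strsplit(lines[loadStart + i], " +")[[1]]))
  new("PCSpace", center = as.numeric(kv("center")),
      scale = as.numeric(kv("scale")), loadings = load,
      eigenvalues = as.numeric(kv("eigenvalues")),
      explainedShare = as.numeric(kv("explained_share")),
      standardised = as.logical(kv("standardised")))
}
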