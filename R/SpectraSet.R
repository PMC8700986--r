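#' Construct a SpectraSet
#'
#' @param spectra numeric matrix, one row per sample, one column per
#'   wavelength (the orientation of the CSV interchange format; stored
#'   internally as wavelengths x samples).
#' @param wavenumbers strictly increasing numeric vector, cm-1, one per
#'   spectral column.
#' @param sampleIds unique sample identifiers.
#' @param animalIds animal identifiers, repeats allowed (deduplication is an
#'   editing step, see \code{\link{deduplicateAnimals}}).
#' @param traits data.frame of per-sample trait values (missing values
#'   allowed before editing); row order must match \code{sampleIds}.
#' @param units \code{"transmittance"} or \code{"absorbance"}.
#' @return A \linkS4class{SpectraSet}.
#' @examples
#' ds <- SpectraSet(matrix(runif(20, 0.1, 1), 4, 5), wavenumbers = 1:5 * 100,
#'                  sampleIds = paste0("s", 1:4), animalIds = paste0("a", 1:4),
#'                  traits = data.frame(ph = c(6.6, 6.7, 6.6, 6.8)))
#' @export
SpectraSet <- function(spectra, wavenumbers, sampleIds, animalIds,
                       traits = NULL, units = c("absorbance", "transmittance")) {
  units <- match.arg(units)
  spectra <- as.matrix(spectra)
  if (ncol(spectra) != length(wavenumbers))
    stop("spectra must have one column per wavenumber")
  if (nrow(spectra) != length(sampleIds))
    stop("spectra must have one row per sample id")
  if (length(animalIds) != length(sampleIds))
    stop("one animal id per sample required")
  sampleIds <- as.character(sampleIds)
  if (anyDuplicated(sampleIds)) stop("sample ids must be unique")
  cd <- S4Vectors::DataFrame(animal_id = as.character(animalIds),
                             row.names = sampleIds)
  if (!is.null(traits)) {
    traits <- as.data.frame(traits)
    if (nrow(traits) != length(sampleIds))
      stop("trait table must have one row per sample")
    for (nm in colnames(traits)) cd[[nm]] <- as.numeric(traits[[nm]])
  }
  mat <- t(spectra)
  dimnames(mat) <- list(NULL, sampleIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(spectra = mat),
    rowData = S4Vectors::DataFrame(wavenumber = as.numeric(wavenumbers)),
    colData = cd)
  new("SpectraSet", se, units = units)
}

#' Wavenumber grid of a SpectraSet
#' @param x a SpectraSet.
#' @return numeric vector of wavenumbers (cm-1).
#' @rdname wavenumbers
#' @export
setMethod("wavenumbers", "SpectraSet", function(x)
  SummarizedExperiment::rowData(x)$wavenumber)

#' Spectral matrix in analysis orientation
#' @param x a SpectraSet.
#' @return numeric matrix, samples x wavelengths, rownames = sample ids.
#' @rdname spectraMatrix
#' @export
setMethod("spectraMatrix", "SpectraSet", function(x)
  t(SummarizedExperiment::assay(x, "spectra")))

#' Animal identifiers
#' @param x a SpectraSet.
#' @rdname animalIds
#' @export
setMethod("animalIds", "SpectraSet", function(x)
  SummarizedExperiment::colData(x)$animal_id)

#' Per-sample trait table
#' @param x a SpectraSet.
#' @return data.frame of trait columns (everything in colData except
#'   animal_id), rownames = sample ids.
#' @rdname traitTable
#' @export
setMethod("traitTable", "SpectraSet", function(x) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  cd[, setdiff(colnames(cd), "animal_id"), drop = FALSE]
})

#' Measurement units of the stored spectra
#' @param x a SpectraSet.
#' @rdname spectraUnits
#' @export
setMethod("spectraUnits", "SpectraSet", function(x) x@units)

#' @export
setMethod("show", "SpectraSet", function(object) {
  cat("SpectraSet:", ncol(object), "samples x", nrow(object), "wavelengths (",
      object@units, ")\n")
  wn <- wavenumbers(object)
  cat("  wavenumbers:", format(min(wn)), "-", format(max(wn)), "cm-1\n")
  tr <- colnames(traitTable(object))
  cat("  traits:", if (length(tr)) paste(tr, collapse = ", ") else "none", "\n")
  cat("  animals:", length(unique(animalIds(object))), "unique\n")
})

sampleIds <- function(x) colnames(x)

## row-subset (samples) keeping class; SummarizedExperiment handles [ already,
## but subsetting by sample works on columns here.
subsetSamples <- function(x, keep) x[, keep]

#' Read a SpectraSet from delimited text files
#'
#' The spectra file has columns \code{sample_id, animal_id} followed by one
#' column per wavenumber (header = the wavenumber value in cm-1).  The
#' optional trait file has \code{sample_id} plus one column per trait and is
#' joined on sample id; empty fields are missing values.
#'
#' @param spectraFile,traitFile paths to CSV files.
#' @param units units of the stored spectral values.
#' @return A \linkS4class{SpectraSet}.
#' @export
readSpectraCSV <- function(spectraFile, traitFile = NULL,
                           units = c("absorbance", "transmittance")) {
  units <- match.arg(units)
  sp <- read.csv(spectraFile, check.names = FALSE)
  if (!all(c("sample_id", "animal_id") %in% colnames(sp)[1:2]))
    stop("spectra file must start with sample_id, animal_id columns")
  wn <- as.numeric(colnames(sp)[-(1:2)])
  if (anyNA(wn)) stop("spectral column headers must be numeric wavenumbers")
  traits <- NULL
  if (!is.null(traitFile)) {
    tr <- read.csv(traitFile, check.names = FALSE)
    if (!"sample_id" %in% colnames(tr))
      stop("trait file must contain a sample_id column")
    idx <- match(as.character(sp$sample_id), as.character(tr$sample_id))
    if (anyNA(idx)) stop("trait file is missing samples: ",
                         paste(head(sp$sample_id[is.na(idx)]), collapse = ", "))
    traits <- tr[idx, setdiff(colnames(tr), "sample_id"), drop = FALSE]
  }
  SpectraSet(as.matrix(sp[, -(1:2), drop = FALSE]), wn,
             sp$sample_id, sp$animal_id, traits, units)
}

#' Write a SpectraSet to delimited text files
#'
#' Emits the same CSV dialect that \code{\link{readSpectraCSV}} accepts,
#' with full-precision floats.
#'
#' @param x a SpectraSet.
#' @param spectraFile,traitFile output paths; the trait file is skipped when
#'   NULL or when \code{x} carries no traits.
#' @return invisibly, the paths written.
#' @export
writeSpectraCSV <- function(x, spectraFile, traitFile = NULL) {
  m <- spectraMatrix(x)
  df <- data.frame(sample_id = sampleIds(x), animal_id = animalIds(x),
                   check.names = FALSE)
  sp <- format(m, digits = 15, trim = TRUE, scientific = FALSE)
  colnames(sp) <- format(wavenumbers(x), digits = 15, trim = TRUE)
  write.csv(cbind(df, as.data.frame(sp, check.names = FALSE)),
            spectraFile, row.names = FALSE, quote = FALSE)
  tt <- traitTable(x)
  if (!is.null(traitFile) && ncol(tt)) {
    out <- data.frame(sample_id = sampleIds(x), check.names = FALSE)
    for (nm in colnames(tt)) {
      vals <- format(tt[[nm]], digits = 15, trim = TRUE, scientific = FALSE)
      vals[is.na(tt[[nm]])] <- ""  # empty field = missing
      out[[nm]] <- vals
    }
    write.csv(out, traitFile, row.names = FALSE, quote = FALSE)
  }
  invisible(c(spectraFile, traitFile))
}
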