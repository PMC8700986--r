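#' @rdname wavenumbers
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname spectraMatrix
#' @export
setGeneric("spectraMatrix", function(x) standardGeneric("spectraMatrix"))

#' @rdname animalIds
#' @export
setGeneric("animalIds", function(x) standardGeneric("animalIds"))

#' @rdname traitTable
#' @export
setGeneric("traitTable", function(x) standardGeneric("traitTable"))

#' @rdname spectraUnits
#' @export
setGeneric("spectraUnits", function(x) standardGeneric("spectraUnits"))

#' @rdname projectScores
#' @export
setGeneric("projectScores", function(space, x) standardGeneric("projectScores"))
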