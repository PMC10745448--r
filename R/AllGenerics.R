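#' @rdname wavelengths
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname designTable
#' @export
setGeneric("designTable", function(x) standardGeneric("designTable"))

#' @rdname spectraMatrix
#' @export
setGeneric("spectraMatrix", function(x) standardGeneric("spectraMatrix"))

#' @rdname correlationMatrix
#' @export
setGeneric("correlationMatrix",
           function(x, tol = 1e-12) standardGeneric("correlationMatrix"))
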