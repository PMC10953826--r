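#' @rdname AssayQC-class
#' @param object,x An object of the documented class.
#' @export
setGeneric("zPrime", function(object) standardGeneric("zPrime"))

#' @rdname ScreenResult-class
#' @export
setGeneric("hitTable", function(object) standardGeneric("hitTable"))

#' @rdname ScreenResult-class
#' @export
setGeneric("wellTable", function(object) standardGeneric("wellTable"))

#' @rdname ScreenResult-class
#' @export
setGeneric("assayQC", function(object) standardGeneric("assayQC"))

#' @rdname ScreenResult-class
#' @export
setGeneric("screenMode", function(object) standardGeneric("screenMode"))

#' @rdname DoseResponseFit-class
#' @export
setGeneric("ic50", function(object) standardGeneric("ic50"))
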