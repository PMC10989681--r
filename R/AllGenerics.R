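#' @rdname GwasSummaryStats-class
#' @param x object.
#' @export
setGeneric("snpData", function(x) standardGeneric("snpData"))

#' @rdname GwasSummaryStats-class
#' @export
setGeneric("trait", function(x) standardGeneric("trait"))

#' @rdname HarmonizedInstruments-class
#' @param x object.
#' @export
setGeneric("instrumentData", function(x) standardGeneric("instrumentData"))

#' @rdname HarmonizedInstruments-class
#' @export
setGeneric("harmonizationLog", function(x) standardGeneric("harmonizationLog"))

#' @rdname HarmonizedInstruments-class
#' @export
setGeneric("nInstruments", function(x) standardGeneric("nInstruments"))

#' @rdname MrScreen-class
#' @param x object.
#' @export
setGeneric("screenSummary", function(x) standardGeneric("screenSummary"))

#' @rdname MrScreen-class
#' @export
setGeneric("screenResults", function(x) standardGeneric("screenResults"))
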