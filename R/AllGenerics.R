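#' @rdname phaseFractions
#' @export
setGeneric("phaseFractions", function(x, ...) standardGeneric("phaseFractions"))

#' @rdname accessors
#' @export
setGeneric("conditionLabel", function(x) standardGeneric("conditionLabel"))

#' @rdname accessors
#' @export
setGeneric("muCCvalue", function(x) standardGeneric("muCCvalue"))

#' @rdname accessors
#' @export
setGeneric("muNbValue", function(x) standardGeneric("muNbValue"))

#' @rdname accessors
#' @export
setGeneric("deltaT", function(x) standardGeneric("deltaT"))

#' @rdname accessors
#' @export
setGeneric("durations", function(x) standardGeneric("durations"))
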