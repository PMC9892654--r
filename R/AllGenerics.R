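#' @rdname abundance
#' @export
setGeneric("abundance", function(x, ...) standardGeneric("abundance"))

#' @rdname responseLabels
#' @export
setGeneric("responseLabels", function(x, ...) standardGeneric("responseLabels"))

#' @rdname responseLabels
#' @export
setGeneric("responseLabels<-",
           function(x, value) standardGeneric("responseLabels<-"))

#' @rdname informativeFeatures
#' @export
setGeneric("informativeFeatures",
           function(x) standardGeneric("informativeFeatures"))

#' @rdname meanAccuracy
#' @export
setGeneric("meanAccuracy", function(x) standardGeneric("meanAccuracy"))

#' @rdname confusionMatrix
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))

#' @rdname classMetrics
#' @export
setGeneric("classMetrics", function(x) standardGeneric("classMetrics"))

#' @rdname selectedFeatures
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' @rdname modelEvaluations
#' @export
setGeneric("modelEvaluations",
           function(x) standardGeneric("modelEvaluations"))

#' @rdname sopTerms
#' @export
setGeneric("sopTerms", function(x) standardGeneric("sopTerms"))

#' @rdname nVariables
#' @export
setGeneric("nVariables", function(x) standardGeneric("nVariables"))

#' @rdname bits
#' @export
setGeneric("bits", function(x) standardGeneric("bits"))

#' @rdname coverage-accessors
#' @export
setGeneric("signatureCoverage",
           function(x) standardGeneric("signatureCoverage"))

#' @rdname coverage-accessors
#' @export
setGeneric("signatureGroup", function(x) standardGeneric("signatureGroup"))
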