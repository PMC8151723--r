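# Accessor generics. Slots are internal; these are the supported surface.

#' @rdname FragmentSpec
#' @export
setGeneric("fragmentName", function(x) standardGeneric("fragmentName"))

#' @rdname FragmentSpec
#' @export
setGeneric("fragmentFormula", function(x) standardGeneric("fragmentFormula"))

#' @rdname FragmentSpec
#' @export
setGeneric("canAcquireLabel", function(x) standardGeneric("canAcquireLabel"))

#' @rdname FragmentSpec
#' @export
setGeneric("labeledElement", function(x) standardGeneric("labeledElement"))

#' @rdname FragmentSpec
#' @export
setGeneric("tracerEnrichment", function(x) standardGeneric("tracerEnrichment"))

#' @rdname FragmentSpec
#' @export
setGeneric("labelEnrichment", function(x) standardGeneric("labelEnrichment"))

#' @rdname FragmentSpec
#' @export
setGeneric("highResElements", function(x) standardGeneric("highResElements"))

#' @rdname FragmentSpec
#' @export
setGeneric("measuredMID", function(x) standardGeneric("measuredMID"))

#' @rdname FragmentSpec
#' @export
setGeneric("measuredMID<-", function(x, value) standardGeneric("measuredMID<-"))

#' @rdname FragmentSpec
#' @export
setGeneric("nLabel", function(x) standardGeneric("nLabel"))

#' @rdname CorrectionResult-accessors
#' @export
setGeneric("correctedMID", function(x) standardGeneric("correctedMID"))

#' @rdname CorrectionResult-accessors
#' @export
setGeneric("sse", function(x) standardGeneric("sse"))

#' @rdname CorrectionResult-accessors
#' @export
setGeneric("correctionMatrix", function(x) standardGeneric("correctionMatrix"))

#' @rdname CorrectionResult-accessors
#' @export
setGeneric("correctionWarnings", function(x) standardGeneric("correctionWarnings"))

#' @rdname AbundanceTable-accessors
#' @export
setGeneric("elementSymbols", function(x) standardGeneric("elementSymbols"))
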