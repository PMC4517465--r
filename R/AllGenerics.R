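#' @rdname enrichment
#' @export
setGeneric("enrichment", function(object, ...) standardGeneric("enrichment"))

#' @rdname enrichment
#' @export
setGeneric("repEnrichment", function(object, ...)
    standardGeneric("repEnrichment"))

#' @rdname classifyBound
#' @export
setGeneric("classifyBound", function(object, cutoff = 4, ...)
    standardGeneric("classifyBound"))

#' @rdname classifyBound
#' @export
setGeneric("boundGenes", function(object, ...) standardGeneric("boundGenes"))

#' @rdname assignRanks
#' @export
setGeneric("assignRanks", function(object, ...) standardGeneric("assignRanks"))

#' @rdname enrichment
#' @export
setGeneric("windowFactors", function(object, ...)
    standardGeneric("windowFactors"))

#' @rdname siteCurve
#' @export
setGeneric("aucDev", function(object) standardGeneric("aucDev"))

#' @rdname siteCurve
#' @export
setGeneric("dMax", function(object) standardGeneric("dMax"))
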