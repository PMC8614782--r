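#' @include AllClasses.R
NULL

#' @rdname featureMatrix
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname featureKind
#' @export
setGeneric("featureKind", function(x) standardGeneric("featureKind"))

#' @rdname sampleIds
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname computeDescriptors
#' @export
setGeneric("computeDescriptors",
           function(record, backend, ...) standardGeneric("computeDescriptors"))

#' @rdname informativeSet
#' @export
setGeneric("informativeSet", function(x) standardGeneric("informativeSet"))

#' @rdname keptFeatures
#' @export
setGeneric("keptFeatures", function(x) standardGeneric("keptFeatures"))

#' @rdname removedFeatures
#' @export
setGeneric("removedFeatures", function(x) standardGeneric("removedFeatures"))

#' @rdname consensusScores
#' @export
setGeneric("consensusScores", function(x) standardGeneric("consensusScores"))

#' @rdname topFeatures
#' @export
setGeneric("topFeatures", function(x, k, ...) standardGeneric("topFeatures"))
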