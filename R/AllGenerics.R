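#' @rdname MetastasisExperiment
#' @param x a package object.
#' @export
setGeneric("lfq", function(x) standardGeneric("lfq"))

#' @rdname MetastasisExperiment
#' @export
setGeneric("metastasisGroup", function(x) standardGeneric("metastasisGroup"))

#' @rdname MetastasisExperiment
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname RankedFeatures-class
#' @param x a `RankedFeatures` object.
#' @export
setGeneric("rankedIds", function(x) standardGeneric("rankedIds"))

#' @rdname RankedFeatures-class
#' @export
setGeneric("featureScores", function(x) standardGeneric("featureScores"))

#' @rdname RfaTrace-class
#' @param x an `RfaTrace` object.
#' @export
setGeneric("chosenFeatures", function(x) standardGeneric("chosenFeatures"))

#' @rdname RfaTrace-class
#' @export
setGeneric("accuracyTrace", function(x) standardGeneric("accuracyTrace"))

#' @rdname ConsensusReport-class
#' @param x a `ConsensusReport` object.
#' @export
setGeneric("selectionCounts", function(x) standardGeneric("selectionCounts"))

#' @rdname ConsensusReport-class
#' @export
setGeneric("consensusSet", function(x) standardGeneric("consensusSet"))

#' @rdname ConsensusReport-class
#' @export
setGeneric("pooledMetrics", function(x) standardGeneric("pooledMetrics"))

#' @rdname ConsensusReport-class
#' @export
setGeneric("foldResults", function(x) standardGeneric("foldResults"))
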