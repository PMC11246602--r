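#' @title Generics for hyperloopR containers
#' @description Accessor generics shared by the S4 containers of the package.
#' @param x an object.
#' @return The accessed component; see the methods of each class.
#' @name hyperloopR-generics
#' @rdname hyperloopR-generics
NULL

#' @rdname hyperloopR-generics
#' @export
setGeneric("chromName", function(x) standardGeneric("chromName"))

#' @rdname hyperloopR-generics
#' @export
setGeneric("binResolution", function(x) standardGeneric("binResolution"))

#' @rdname hyperloopR-generics
#' @export
setGeneric("numBins", function(x) standardGeneric("numBins"))

#' @rdname hyperloopR-generics
#' @export
setGeneric("clusterBins", function(x) standardGeneric("clusterBins"))

#' @rdname hyperloopR-generics
#' @export
setGeneric("clusterIds", function(x) standardGeneric("clusterIds"))

#' @rdname hyperloopR-generics
#' @export
setGeneric("numClusters", function(x) standardGeneric("numClusters"))

#' @rdname hyperloopR-generics
#' @export
setGeneric("contactPairs", function(x) standardGeneric("contactPairs"))

#' @rdname hyperloopR-generics
#' @export
setGeneric("totalContacts", function(x) standardGeneric("totalContacts"))

#' @rdname hyperloopR-generics
#' @export
setGeneric("biasValues", function(x) standardGeneric("biasValues"))

#' @rdname hyperloopR-generics
#' @export
setGeneric("validBins", function(x) standardGeneric("validBins"))

#' @rdname hyperloopR-generics
#' @export
setGeneric("loopPairs", function(x) standardGeneric("loopPairs"))

#' @rdname hyperloopR-generics
#' @export
setGeneric("loopAnchors", function(x) standardGeneric("loopAnchors"))

#' @rdname hyperloopR-generics
#' @export
setGeneric("numLoops", function(x) standardGeneric("numLoops"))

#' @rdname hyperloopR-generics
#' @export
setGeneric("trialCounts", function(x) standardGeneric("trialCounts"))

#' @rdname hyperloopR-generics
#' @export
setGeneric("distanceDistributions", function(x) standardGeneric("distanceDistributions"))
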