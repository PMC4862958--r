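#' @rdname TrialArray-class
#' @param x,object a package object.
#' @export
setGeneric("trialData", function(x) standardGeneric("trialData"))

#' @rdname TrialArray-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname TrialArray-class
#' @export
setGeneric("timeOrigin", function(x) standardGeneric("timeOrigin"))

#' @rdname TrialArray-class
#' @export
setGeneric("seriesKind", function(x) standardGeneric("seriesKind"))

#' @rdname TrialArray-class
#' @export
setGeneric("seriesLabels", function(x) standardGeneric("seriesLabels"))

#' @rdname TrialArray-class
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname TrialArray-class
#' @export
setGeneric("nSeries", function(x) standardGeneric("nSeries"))

#' @rdname TrialArray-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname TrialArray-class
#' @export
setGeneric("trialTimes", function(x) standardGeneric("trialTimes"))

#' @rdname TrialArray-class
#' @export
setGeneric("metadata", function(x) standardGeneric("metadata"))

#' @rdname TrialArray-class
#' @param value replacement value.
#' @export
setGeneric("metadata<-", function(x, value) standardGeneric("metadata<-"))

#' @rdname SuperAdjacency-class
#' @param x a [SuperAdjacency-class].
#' @export
setGeneric("bandNames", function(x) standardGeneric("bandNames"))

#' @rdname SuperAdjacency-class
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' @rdname SuperAdjacency-class
#' @param seedBand,testBand band names selecting a tile.
#' @export
setGeneric("getTile", function(x, seedBand, testBand)
  standardGeneric("getTile"))

#' Extract the matrix payload of a result object
#'
#' @param x a [Tile-class], [SuperAdjacency-class] or
#'   [PermutationResult-class].
#' @return The underlying numeric matrix (with dimnames where defined).
#' @export
setGeneric("as.matrix")
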