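#' @rdname FeatureTable-class
#' @param object,x an object of the documented class
#' @export
setGeneric("arrayId", function(x) standardGeneric("arrayId"))

#' @rdname FeatureTable-class
#' @export
setGeneric("featureData", function(x) standardGeneric("featureData"))

#' @rdname FeatureTable-class
#' @export
setGeneric("parseReport", function(x) standardGeneric("parseReport"))

#' @rdname ChannelMatrix
#' @param x a `ChannelMatrix`
#' @export
setGeneric("channelName", function(x) standardGeneric("channelName"))

#' @rdname ChannelMatrix
#' @export
setGeneric("probeIds", function(x) standardGeneric("probeIds"))

#' @rdname ChannelMatrix
#' @export
setGeneric("arrayIds", function(x) standardGeneric("arrayIds"))

#' @rdname ChannelMatrix
#' @export
setGeneric("signalValues", function(x) standardGeneric("signalValues"))

#' @rdname ChannelMatrix
#' @export
setGeneric("isNegativeControl", function(x) standardGeneric("isNegativeControl"))

#' @rdname MDSResult-class
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname MDSResult-class
#' @export
setGeneric("mdsPoints", function(x) standardGeneric("mdsPoints"))

#' @rdname MDSResult-class
#' @export
setGeneric("goodnessCurve", function(x) standardGeneric("goodnessCurve"))

#' @rdname MDSResult-class
#' @export
setGeneric("selectedK", function(x) standardGeneric("selectedK"))

#' @rdname BackgroundModel-class
#' @export
setGeneric("backgroundStatistic", function(x) standardGeneric("backgroundStatistic"))

#' @rdname BackgroundModel-class
#' @export
setGeneric("pooledBackground", function(x) standardGeneric("pooledBackground"))

#' @rdname CallCurve-class
#' @export
setGeneric("callThresholds", function(x) standardGeneric("callThresholds"))

#' @rdname CallCurve-class
#' @export
setGeneric("fractionOn", function(x) standardGeneric("fractionOn"))

#' @rdname VarianceReport-class
#' @export
setGeneric("probeStats", function(x) standardGeneric("probeStats"))

#' @rdname VarianceReport-class
#' @export
setGeneric("reportSummary", function(x) standardGeneric("reportSummary"))
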