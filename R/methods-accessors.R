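#' @rdname FeatureTable-class
setMethod("arrayId", "FeatureTable", function(x) x@arrayId)

#' @rdname FeatureTable-class
setMethod("featureData", "FeatureTable", function(x) x@features)

#' @rdname FeatureTable-class
setMethod("parseReport", "FeatureTable", function(x)
  list(nDropped = x@nDropped, lines = x@parseReport))

setMethod("show", "FeatureTable", function(object) {
  f <- object@features
  cat("FeatureTable for array '", object@arrayId, "'\n", sep = "")
  cat("  ", nrow(f), " features (",
      sum(f$controlType == 0L), " experimental, ",
      sum(f$controlType != 0L), " control); ",
      object@nDropped, " rows dropped at parse\n", sep = "")
})

#' @rdname ChannelMatrix
setMethod("channelName", "ChannelMatrix", function(x) metadata(x)$channel)

#' @rdname ChannelMatrix
setMethod("probeIds", "ChannelMatrix", function(x) rownames(x))

#' @rdname ChannelMatrix
setMethod("arrayIds", "ChannelMatrix", function(x) colnames(x))

#' @rdname ChannelMatrix
setMethod("signalValues", "ChannelMatrix", function(x) assay(x, "signal"))

#' @rdname ChannelMatrix
setMethod("isNegativeControl", "ChannelMatrix", function(x)
  rowData(x)$isNegativeControl)

setMethod("show", "ChannelMatrix", function(object) {
  cat("ChannelMatrix: ", nrow(object), " probes x ", ncol(object),
      " arrays [", metadata(object)$channel, ", ",
      metadata(object)$scale, " scale]\n", sep = "")
  if (any(rowData(object)$isNegativeControl))
    cat("  negative-control probe: ",
        paste(rownames(object)[rowData(object)$isNegativeControl],
              collapse = ", "), "\n", sep = "")
  norm <- metadata(object)$normalization
  if (!is.null(norm))
    cat("  normalized: ", norm, "\n", sep = "")
})

setMethod("show", "NormalizationModel", function(object) {
  cat("NormalizationModel [", object@method, "]", sep = "")
  if (nzchar(object@arrayId)) cat(" for array '", object@arrayId, "'", sep = "")
  cat("\n")
  switch(object@method,
    linear = cat(sprintf("  intercept = %.4f, slope = %.4f\n",
                         object@intercept, object@slope)),
    loess = cat("  curve of", nrow(object@curve), "fitted points over x in [",
                sprintf("%.3f, %.3f", min(object@curve$x),
                        max(object@curve$x)), "]\n"),
    quantile = cat("  rank-mean template of", length(object@template),
                   "values\n"))
})

#' @rdname VarianceReport-class
setMethod("probeStats", "VarianceReport", function(x) x@probeStats)

#' @rdname VarianceReport-class
setMethod("reportSummary", "VarianceReport", function(x) x@summary)

setMethod("show", "VarianceReport", function(object) {
  s <- object@summary
  cat("VarianceReport over", nrow(object@probeStats), "probes,",
      object@nArrays, "arrays\n")
  cat(sprintf("  mean SD Cy5 = %.3f, mean SD Cy3 = %.3f\n",
              s$meanSdCy5, s$meanSdCy3))
  cat(sprintf("  mean covariance = %.3f, mean correlation = %.3f\n",
              s$meanCov, s$meanCor))
  cat(sprintf("  SD of Cy5 - Cy3 difference (covariance-corrected) = %.3f\n",
              s$sdDifference))
})

#' @rdname BackgroundModel-class
setMethod("backgroundStatistic", "BackgroundModel", function(x) x@statistic)

#' @rdname BackgroundModel-class
setMethod("pooledBackground", "BackgroundModel", function(x) x@pooled)

setMethod("show", "BackgroundModel", function(object) {
  cat("BackgroundModel from control probe '", object@controlProbe,
      "'\n", sep = "")
  cat(sprintf("  %d arrays; background statistic %.3f-%.3f log2 units; %d pooled signals\n",
              length(object@statistic), min(object@statistic),
              max(object@statistic), length(object@pooled)))
})

#' @rdname CallCurve-class
setMethod("callThresholds", "CallCurve", function(x) x@thresholds)

#' @rdname CallCurve-class
setMethod("fractionOn", "CallCurve", function(x) x@fractionOn)

setMethod("show", "CallCurve", function(object) {
  cat("CallCurve over", object@nProbes, "probes at",
      length(object@thresholds), "thresholds\n")
  i <- which.min(abs(object@thresholds - 0.5))
  cat(sprintf("  %.1f%% of probes 'on' at threshold %.2f log2 units above background\n",
              100 * object@fractionOn[i], object@thresholds[i]))
})

#' @rdname MDSResult-class
setMethod("eigenvalues", "MDSResult", function(x) x@eigenvalues)

#' @rdname MDSResult-class
setMethod("mdsPoints", "MDSResult", function(x) x@points)

#' @rdname MDSResult-class
setMethod("goodnessCurve", "MDSResult", function(x) x@pk)

#' @rdname MDSResult-class
setMethod("selectedK", "MDSResult", function(x) x@selectedK)

setMethod("show", "MDSResult", function(object) {
  cat("MDSResult:", nrow(object@points), "arrays embedded in",
      ncol(object@points), "dimensions\n")
  cat(sprintf("  selected k = %d at goodness-of-fit cutoff %.2f (P_k = %.3f)\n",
              object@selectedK, object@cutoff,
              object@pk[min(object@selectedK, length(object@pk))]))
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nProbes, "probes x", object@nArrays, "arrays\n")
  cat("  ", object@nReplicateProbes, " probes replicated ",
      object@replicateCount, "x; negative control '",
      object@negativeControlProbe, "' x", object@negativeControlCount,
      "\n", sep = "")
  cat(sprintf("  noise SD Cy3/Cy5 = %.2f/%.2f (cov %.2f); expressed fraction %.2f; seed %d\n",
              object@noiseSdCy3, object@noiseSdCy5, object@channelCov,
              object@expressedFraction, object@seed))
})
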