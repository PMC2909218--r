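#' @import methods
#' @importFrom S4Vectors metadata metadata<- DataFrame SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' One scanned array as parsed from a Feature Extraction file
#'
#' A `FeatureTable` holds the per-feature records of a single two-colour
#' array: probe name, control type and the Cy3 (green) and Cy5 (red) median
#' signals, together with a parse report describing any rows that were
#' dropped during parsing.
#'
#' @slot arrayId single string identifying the array (unique within a
#'   dataset; defaults to the file base name).
#' @slot features `data.frame` with columns `featureIndex`, `probeName`,
#'   `controlType`, `gMedianSignal`, `rMedianSignal`. Control type 0 marks
#'   an experimental probe; any other value marks a control feature.
#' @slot parseReport character vector of log lines describing dropped rows.
#' @slot nDropped number of data rows dropped (non-numeric or non-positive
#'   signals).
#'
#' @seealso [readFeatureExtraction()]
#' @export
setClass("FeatureTable",
  representation(
    arrayId = "character",
    features = "data.frame",
    parseReport = "character",
    nDropped = "integer"
  ),
  prototype(parseReport = character(0), nDropped = 0L)
)

setValidity("FeatureTable", function(object) {
  msg <- character(0)
  f <- object@features
  need <- c("featureIndex", "probeName", "controlType",
            "gMedianSignal", "rMedianSignal")
  if (length(object@arrayId) != 1L || !nzchar(object@arrayId))
    msg <- c(msg, "'arrayId' must be a single non-empty string")
  if (!all(need %in% names(f)))
    msg <- c(msg, paste0("'features' must have columns: ",
                         paste(need, collapse = ", ")))
  else {
    if (nrow(f) == 0L)
      msg <- c(msg, "'features' must contain at least one record")
    if (nrow(f) > 0L) {
      if (any(!is.finite(f$gMedianSignal)) || any(f$gMedianSignal <= 0))
        msg <- c(msg, "all gMedianSignal values must be finite and > 0")
      if (any(!is.finite(f$rMedianSignal)) || any(f$rMedianSignal <= 0))
        msg <- c(msg, "all rMedianSignal values must be finite and > 0")
      if (any(is.na(f$probeName)) || any(!nzchar(f$probeName)))
        msg <- c(msg, "all probe names must be non-empty")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Probe-by-array signal matrix for one channel
#'
#' `ChannelMatrix` extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with a single assay `"signal"` holding one channel's probe-by-array
#' signal values, on the log2 scale unless the `scale` metadata says
#' otherwise. Row data carries an `isNegativeControl` flag for the
#' collapsed negative-control background probe.
#'
#' @seealso [buildChannelMatrix()], [normalizeToReference()]
#' @export
setClass("ChannelMatrix", contains = "SummarizedExperiment")

setValidity("ChannelMatrix", function(object) {
  msg <- character(0)
  if (length(SummarizedExperiment::assayNames(object)) != 1L ||
      SummarizedExperiment::assayNames(object)[1L] != "signal")
    msg <- c(msg, "must carry exactly one assay named 'signal'")
  v <- assay(object, withDimnames = FALSE)
  if (!is.numeric(v) || any(!is.finite(v)))
    msg <- c(msg, "signal values must be numeric and finite")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "probe ids must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "array ids must be present and unique")
  ch <- metadata(object)$channel
  if (!is.null(ch) && !ch %in% c("Cy3", "Cy5"))
    msg <- c(msg, "channel must be 'Cy3' or 'Cy5'")
  if (length(msg)) msg else TRUE
})

#' Construct a ChannelMatrix
#'
#' @param values numeric probe-by-array matrix with row and column names
#'   (or `probeIds`/`arrayIds` supplied).
#' @param channel `"Cy3"` (green, reference) or `"Cy5"` (red,
#'   experimental).
#' @param probeIds,arrayIds optional dimension names overriding those of
#'   `values`.
#' @param isNegativeControl optional logical vector flagging the
#'   negative-control background probe row(s); defaults to all `FALSE`.
#' @param scale `"log2"` or `"raw"`; purely descriptive metadata.
#' @return A [ChannelMatrix-class] object.
#' @examples
#' m <- matrix(rnorm(6, 8), 3, 2,
#'             dimnames = list(paste0("p", 1:3), c("a1", "a2")))
#' cm <- ChannelMatrix(m, channel = "Cy3")
#' channelName(cm)
#' @export
ChannelMatrix <- function(values, channel = c("Cy3", "Cy5"),
                          probeIds = rownames(values),
                          arrayIds = colnames(values),
                          isNegativeControl = NULL,
                          scale = "log2") {
  channel <- match.arg(channel)
  values <- as.matrix(values)
  if (is.null(probeIds) || is.null(arrayIds))
    stop("probe and array ids are required")
  dimnames(values) <- list(probeIds, arrayIds)
  if (is.null(isNegativeControl))
    isNegativeControl <- rep(FALSE, nrow(values))
  se <- SummarizedExperiment(
    assays = SimpleList(signal = values),
    rowData = DataFrame(isNegativeControl = isNegativeControl,
                        row.names = probeIds),
    metadata = list(channel = channel, scale = scale)
  )
  new("ChannelMatrix", se)
}

#' Fitted per-array normalization model
#'
#' Captures the correction fitted for one array against the per-probe mean
#' reference: intercept/slope for the global linear method, a lookup curve
#' of `(x, fitted)` pairs for the segmented locally-linear (LOESS) method,
#' or the rank-mean template for quantile normalization.
#'
#' @slot method `"linear"`, `"loess"` or `"quantile"`.
#' @slot arrayId array the model was fitted for (empty for quantile, which
#'   is fitted jointly).
#' @slot intercept,slope linear model coefficients (`NA` otherwise).
#' @slot curve `data.frame` with columns `x` and `fitted`; the smooth is
#'   evaluated by linear interpolation between these points.
#' @slot template numeric rank-mean template (quantile method only).
#' @export
setClass("NormalizationModel",
  representation(
    method = "character",
    arrayId = "character",
    intercept = "numeric",
    slope = "numeric",
    curve = "data.frame",
    template = "numeric"
  ),
  prototype(intercept = NA_real_, slope = NA_real_,
            curve = data.frame(x = numeric(0), fitted = numeric(0)),
            template = numeric(0), arrayId = "")
)

setValidity("NormalizationModel", function(object) {
  msg <- character(0)
  if (!object@method %in% c("linear", "loess", "quantile"))
    msg <- c(msg, "method must be 'linear', 'loess' or 'quantile'")
  if (object@method == "linear" &&
      (!is.finite(object@intercept) || !is.finite(object@slope)))
    msg <- c(msg, "linear model needs finite intercept and slope")
  if (object@method == "loess") {
    cv <- object@curve
    if (nrow(cv) < 2L || any(!is.finite(cv$x)) || any(!is.finite(cv$fitted)))
      msg <- c(msg, "loess model needs a finite curve of >= 2 points")
    else if (is.unsorted(cv$x, strictly = TRUE))
      msg <- c(msg, "loess curve x values must be strictly increasing")
  }
  if (object@method == "quantile" && length(object@template) == 0L)
    msg <- c(msg, "quantile model needs a non-empty template")
  if (length(msg)) msg else TRUE
})

#' Variance / quality-control report for a pair of channels
#'
#' @slot probeStats per-probe `data.frame`: mean and sample SD per channel,
#'   between-channel sample covariance and Pearson correlation.
#' @slot summary named list of summary statistics (average SD per channel,
#'   average covariance, average correlation, SD of the Cy5 - Cy3
#'   difference via the covariance-corrected formula, SD percentiles).
#' @slot nArrays number of arrays the statistics were computed across.
#' @export
setClass("VarianceReport",
  representation(
    probeStats = "data.frame",
    summary = "list",
    nArrays = "integer"
  )
)

#' Background model from negative-control features
#'
#' @slot statistic named numeric, one background level (log2) per array.
#' @slot pooled numeric vector of all negative-control log2 signals that
#'   entered the model, for plotting the background distribution.
#' @slot controlProbe name of the negative-control probe used.
#' @export
setClass("BackgroundModel",
  representation(
    statistic = "numeric",
    pooled = "numeric",
    controlProbe = "character"
  )
)

setValidity("BackgroundModel", function(object) {
  msg <- character(0)
  if (length(object@statistic) == 0L || any(!is.finite(object@statistic)))
    msg <- c(msg, "background statistic must be finite and non-empty")
  if (length(object@pooled) == 0L)
    msg <- c(msg, "pooled background distribution must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Expressed-gene call curve over a sweep of thresholds
#'
#' @slot thresholds ascending thresholds in log2 units above the background
#'   statistic.
#' @slot fractionOn fraction of probes scored "on" (signal strictly above
#'   background + threshold) at each threshold.
#' @slot nProbes number of probes entering the call.
#' @export
setClass("CallCurve",
  representation(
    thresholds = "numeric",
    fractionOn = "numeric",
    nProbes = "integer"
  )
)

setValidity("CallCurve", function(object) {
  msg <- character(0)
  if (length(object@thresholds) != length(object@fractionOn))
    msg <- c(msg, "thresholds and fractionOn must have equal length")
  if (is.unsorted(object@thresholds))
    msg <- c(msg, "thresholds must be sorted ascending")
  f <- object@fractionOn
  if (any(f < 0 | f > 1))
    msg <- c(msg, "fractionOn must lie in [0, 1]")
  if (length(f) > 1L && any(diff(f) > 1e-12))
    msg <- c(msg, "fractionOn must be non-increasing in threshold")
  if (length(msg)) msg else TRUE
})

#' Classical multidimensional scaling result
#'
#' @slot eigenvalues all eigenvalues of the double-centred squared-distance
#'   matrix, in descending order (may include negatives from numerical
#'   error; these are clamped to zero in the goodness of fit).
#' @slot points array-by-dimension coordinate matrix for the retained
#'   positive eigenvalues (each axis scaled by the square root of its
#'   eigenvalue; axis sign fixed so the largest-magnitude loading is
#'   positive).
#' @slot pk cumulative goodness-of-fit value per dimension.
#' @slot selectedK smallest dimensionality reaching the cutoff.
#' @slot cutoff the goodness-of-fit cutoff used for selection.
#' @slot annotations per-array annotation `data.frame` carried through for
#'   plotting (may be empty).
#' @export
setClass("MDSResult",
  representation(
    eigenvalues = "numeric",
    points = "matrix",
    pk = "numeric",
    selectedK = "integer",
    cutoff = "numeric",
    annotations = "data.frame"
  ),
  prototype(annotations = data.frame())
)

setValidity("MDSResult", function(object) {
  msg <- character(0)
  if (is.unsorted(rev(object@eigenvalues)))
    msg <- c(msg, "eigenvalues must be in descending order")
  p <- object@pk
  if (length(p) && (any(p < -1e-12 | p > 1 + 1e-12) || any(diff(p) < -1e-12)))
    msg <- c(msg, "pk must be non-decreasing within [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic array generator
#'
#' See [simConfig()] for the meaning and defaults of each slot.
#'
#' @export
setClass("SimConfig",
  representation(
    nProbes = "integer",
    nReplicateProbes = "integer",
    replicateCount = "integer",
    negativeControlCount = "integer",
    nArrays = "integer",
    meanLog2 = "numeric",
    probeSd = "numeric",
    noiseSdCy3 = "numeric",
    noiseSdCy5 = "numeric",
    channelCov = "numeric",
    intraSdCy3 = "numeric",
    intraSdCy5 = "numeric",
    intraCov = "numeric",
    offsetRange = "numeric",
    slopeRange = "numeric",
    curvatureRange = "numeric",
    biasCenter = "numeric",
    expressedFraction = "numeric",
    stimulatedFraction = "numeric",
    stimulationEffect = "numeric",
    backgroundLog2 = "numeric",
    backgroundSd = "numeric",
    groupLabels = "character",
    groupEffect = "numeric",
    groupProbeFraction = "numeric",
    negativeControlProbe = "character",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (object@nProbes < 1L || object@nArrays < 1L ||
      object@replicateCount < 2L || object@negativeControlCount < 2L)
    msg <- c(msg, "all counts must be positive (replicate/control >= 2)")
  if (object@nReplicateProbes < 0L || object@nReplicateProbes > object@nProbes)
    msg <- c(msg, "nReplicateProbes must lie in [0, nProbes]")
  if (object@channelCov^2 > object@noiseSdCy3^2 * object@noiseSdCy5^2)
    msg <- c(msg, "invalid channel covariance: channelCov^2 must not exceed noiseSdCy3^2 * noiseSdCy5^2")
  if (object@intraCov^2 > object@intraSdCy3^2 * object@intraSdCy5^2)
    msg <- c(msg, "invalid intra-array covariance")
  for (f in c("expressedFraction", "stimulatedFraction", "groupProbeFraction"))
    if (slot(object, f) < 0 || slot(object, f) > 1)
      msg <- c(msg, paste0(f, " must lie in [0, 1]"))
  if (length(object@groupLabels) &&
      length(object@groupLabels) != object@nArrays)
    msg <- c(msg, "groupLabels must have one label per array")
  if (length(object@slopeRange) != 2L || object@slopeRange[1] > object@slopeRange[2])
    msg <- c(msg, "slopeRange must be c(lo, hi)")
  if (length(msg)) msg else TRUE
})
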