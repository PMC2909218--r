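#' Fit a background model from negative-control features
#'
#' The negative-control probe has no target in the hybridised sample, so
#' its signal estimates non-specific background hybridisation. The
#' per-array background statistic is the mean of the negative-control log2
#' signals (the collapsed replicate value); the pooled distribution across
#' arrays is retained for plotting.
#'
#' @param x a [FeatureTable-class] (raw control features of one array) or a
#'   [ChannelMatrix-class] whose rows include the collapsed
#'   negative-control probe.
#' @param channel which channel to use for a `FeatureTable`.
#' @param controlProbe negative-control probe name.
#' @param statistic `"mean"` (default) or `"median"` of the control
#'   signals.
#' @return A [BackgroundModel-class].
#' @export
setGeneric("fitBackground", function(x, ...) standardGeneric("fitBackground"))

#' @rdname fitBackground
#' @param ... passed to methods.
setMethod("fitBackground", "FeatureTable",
  function(x, channel = c("Cy3", "Cy5"), controlProbe = "(-)3xSLv1",
           statistic = c("mean", "median")) {
    channel <- match.arg(channel)
    statistic <- match.arg(statistic)
    f <- featureData(x)
    ctl <- f[f$probeName == controlProbe, , drop = FALSE]
    if (nrow(ctl) < 2L)
      stop("no negative-control features found: expected probe '",
           controlProbe, "'")
    sig <- log2Transform(
      if (channel == "Cy3") ctl$gMedianSignal else ctl$rMedianSignal)
    stat <- if (statistic == "mean") mean(sig) else stats::median(sig)
    new("BackgroundModel",
        statistic = stats::setNames(stat, arrayId(x)),
        pooled = sig, controlProbe = controlProbe)
  })

#' @rdname fitBackground
setMethod("fitBackground", "ChannelMatrix",
  function(x, controlProbe = "(-)3xSLv1", statistic = c("mean", "median")) {
    statistic <- match.arg(statistic)
    hit <- isNegativeControl(x) | probeIds(x) == controlProbe
    if (!any(hit))
      stop("no negative-control row found: expected probe '",
           controlProbe, "'")
    v <- signalValues(x)[hit, , drop = FALSE]
    stat <- if (statistic == "mean") colMeans(v)
            else apply(v, 2L, stats::median)
    new("BackgroundModel", statistic = stat, pooled = as.numeric(v),
        controlProbe = controlProbe)
  })

#' Sweep an on/off expression call over thresholds
#'
#' A probe is scored "on" when its log2 signal lies strictly above the
#' background statistic plus the threshold; the fraction of probes "on" is
#' reported for each threshold.
#'
#' @param x numeric vector of log2 signals for one sample (or the average
#'   of several samples).
#' @param bg a [BackgroundModel-class] or a single numeric background level
#'   (log2 units).
#' @param thresholds ascending thresholds (log2 units above background).
#' @param arrayId which array's background statistic to use when `bg` holds
#'   several; ignored for a scalar `bg`.
#' @param pooled use the mean of the per-array background statistics
#'   instead of a single array's.
#' @return A [CallCurve-class].
#' @export
callExpressed <- function(x, bg, thresholds = seq(0, 1, by = 0.1),
                          arrayId = NULL, pooled = FALSE) {
  if (is.unsorted(thresholds))
    stop("thresholds must be sorted ascending")
  stat <- if (is(bg, "BackgroundModel")) {
    s <- backgroundStatistic(bg)
    if (pooled) mean(s)
    else if (length(s) == 1L) s
    else if (!is.null(arrayId) && arrayId %in% names(s)) s[[arrayId]]
    else stop("background model holds several arrays; give 'arrayId' or pooled = TRUE")
  } else if (is.numeric(bg) && length(bg) == 1L) bg
  else stop("'bg' must be a BackgroundModel or a single number")
  frac <- vapply(thresholds, function(th) mean(x > stat + th), numeric(1))
  new("CallCurve", thresholds = as.numeric(thresholds),
      fractionOn = frac, nProbes = length(x))
}

#' Cross-channel interference at high stimulation indices
#'
#' Given matched per-probe differences between a stimulated and an
#' unstimulated sample in each channel (the stimulation indices, log2
#' units), quantifies how much of the experimental-channel response leaks
#' into the reference channel: within bins of the Cy5 difference, the
#' Pearson correlation and OLS slope of the Cy3 difference on the Cy5
#' difference, plus the same correlation over the `topN` largest Cy5
#' differences.
#'
#' @param d5 per-probe Cy5 differences (stimulated - unstimulated, log2,
#'   normalized data).
#' @param d3 matching Cy3 differences.
#' @param bins list of `c(lo, hi)` intervals, interpreted as `(lo, hi]` on
#'   `d5`; must be disjoint.
#' @param topN size of the top-stimulation-index subset (default 50).
#' @return list with `bins` (data.frame: lo, hi, count, correlation,
#'   slope; bins with fewer than 3 probes report `NA`) and `top`
#'   (list: n, correlation, slope).
#' @export
channelInterference <- function(d5, d3,
                                bins = list(c(2.5, 3), c(3, 4), c(4, Inf)),
                                topN = 50L) {
  if (length(d5) != length(d3))
    stop("d5 and d3 must be matched per probe")
  b <- do.call(rbind, lapply(bins, function(bb) data.frame(lo = bb[1],
                                                           hi = bb[2])))
  b <- b[order(b$lo), , drop = FALSE]
  if (nrow(b) > 1L && any(b$lo[-1L] < b$hi[-nrow(b)]))
    stop("bins must be disjoint")
  stats_ <- lapply(seq_len(nrow(b)), function(i) {
    idx <- d5 > b$lo[i] & d5 <= b$hi[i]
    n <- sum(idx)
    if (n < 3L) return(c(n, NA_real_, NA_real_))
    c(n, stats::cor(d5[idx], d3[idx]),
      unname(stats::coef(stats::lm(d3[idx] ~ d5[idx]))[2L]))
  })
  sm <- do.call(rbind, stats_)
  out <- data.frame(lo = b$lo, hi = b$hi, count = as.integer(sm[, 1L]),
                    correlation = sm[, 2L], slope = sm[, 3L])
  topIdx <- order(d5, decreasing = TRUE)[seq_len(min(topN, length(d5)))]
  top <- list(n = length(topIdx),
              correlation = if (length(topIdx) >= 3L)
                stats::cor(d5[topIdx], d3[topIdx]) else NA_real_,
              slope = if (length(topIdx) >= 3L)
                unname(stats::coef(stats::lm(d3[topIdx] ~ d5[topIdx]))[2L])
              else NA_real_)
  list(bins = out, top = top)
}
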