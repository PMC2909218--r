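#' Base-2 logarithm of a positive signal
#'
#' Median fluorescence signals span several orders of magnitude and have a
#' magnitude-dependent SD on the raw scale; the log2 transform stabilises
#' the SD and improves per-probe normality, so every downstream statistic
#' works in log2 units.
#'
#' @param v positive numeric vector.
#' @return `log2(v)`.
#' @export
log2Transform <- function(v) {
  if (any(!is.finite(v)) || any(v <= 0))
    stop("log2 transform requires strictly positive finite signals; ",
         "non-positive values should have been dropped at parse time")
  log2(v)
}

#' Collapse replicate probes within one array
#'
#' Log2-transforms one channel of a [FeatureTable-class] and averages the
#' features that share a probe name (replicated probes are spotted at
#' several positions of the array). The collapse takes the arithmetic mean
#' of the log2 signals; per-group sample SDs are returned as a replicate
#' report, whose average is the within-array measurement error. The
#' negative-control background probe is collapsed like any other and kept
#' in the output (flagged), while all other control features are excluded.
#'
#' @param t a [FeatureTable-class].
#' @param channel `"Cy3"` or `"Cy5"`.
#' @param negativeControlProbe probe name of the negative control kept in
#'   the output.
#' @return list with `values` (named numeric, one collapsed log2 value per
#'   probe, sorted by probe id), `isNegativeControl` (logical, parallel to
#'   `values`), `report` (data.frame `probe`, `mean`, `sd`, `count` for
#'   every replicated group) and `meanReplicateSd` (the array's average
#'   within-array replicate SD).
#' @examples
#' cfg <- simConfig(nProbes = 100, nReplicateProbes = 10,
#'                  negativeControlCount = 10, nArrays = 1, seed = 3)
#' d <- generateDataset(cfg, dir = tempfile())
#' ft <- readFeatureExtraction(d$files[1])
#' cc <- collapseReplicates(ft, "Cy3")
#' cc$meanReplicateSd
#' @export
collapseReplicates <- function(t, channel = c("Cy3", "Cy5"),
                               negativeControlProbe = "(-)3xSLv1") {
  channel <- match.arg(channel)
  f <- featureData(t)
  keep <- f$controlType == 0L | f$probeName == negativeControlProbe
  f <- f[keep, , drop = FALSE]
  sig <- if (channel == "Cy3") f$gMedianSignal else f$rMedianSignal
  x <- log2Transform(sig)
  probe <- f$probeName
  means <- tapply(x, probe, mean)
  sds <- tapply(x, probe, stats::sd)
  counts <- tapply(x, probe, length)
  ord <- order(names(means))
  means <- means[ord]; sds <- sds[ord]; counts <- counts[ord]
  repl <- counts >= 2L
  report <- data.frame(probe = names(means)[repl],
                       mean = unname(means[repl]),
                       sd = unname(sds[repl]),
                       count = unname(as.integer(counts[repl])),
                       stringsAsFactors = FALSE)
  list(values = stats::setNames(as.numeric(means), names(means)),
       isNegativeControl = names(means) == negativeControlProbe,
       report = report,
       meanReplicateSd = if (nrow(report)) mean(report$sd) else NA_real_)
}

#' Assemble a per-channel expression matrix from several arrays
#'
#' Applies [collapseReplicates()] to every array and binds the collapsed
#' columns into a [ChannelMatrix-class]. All arrays must contain the same
#' probe set.
#'
#' @param tables list of [FeatureTable-class] objects (as returned by
#'   [readFeatureExtractionDir()]).
#' @inheritParams collapseReplicates
#' @return A [ChannelMatrix-class]; metadata carries the per-array
#'   replicate reports (`replicateReports`) and the per-array average
#'   replicate SD (`meanReplicateSd`).
#' @export
buildChannelMatrix <- function(tables, channel = c("Cy3", "Cy5"),
                               negativeControlProbe = "(-)3xSLv1") {
  channel <- match.arg(channel)
  if (length(tables) < 1L) stop("need at least one FeatureTable")
  collapsed <- lapply(tables, collapseReplicates, channel = channel,
                      negativeControlProbe = negativeControlProbe)
  ids <- vapply(tables, arrayId, character(1))
  if (anyDuplicated(ids)) stop("duplicate array ids")
  probes <- names(collapsed[[1L]]$values)
  for (cc in collapsed)
    if (!identical(names(cc$values), probes))
      stop("arrays do not share a common probe set")
  v <- vapply(collapsed, `[[`, numeric(length(probes)), "values")
  dimnames(v) <- list(probes, ids)
  m <- ChannelMatrix(v, channel = channel,
                     isNegativeControl = collapsed[[1L]]$isNegativeControl)
  metadata(m)$replicateReports <- lapply(collapsed, `[[`, "report")
  metadata(m)$meanReplicateSd <-
    stats::setNames(vapply(collapsed, `[[`, numeric(1), "meanReplicateSd"),
                    ids)
  m
}
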