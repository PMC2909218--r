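#' Per-probe mean reference across arrays
#'
#' The normalization target: for each probe, the arithmetic mean of its
#' log2 signal over all arrays. Each array is then regressed on this
#' reference and the fitted systematic deviation from the identity line is
#' subtracted.
#'
#' @param m a [ChannelMatrix-class] or numeric probe-by-array matrix with
#'   at least two arrays.
#' @return named numeric vector of per-probe means.
#' @export
meanReference <- function(m) {
  v <- .signalOf(m)
  if (ncol(v) < 2L) stop("mean reference needs at least 2 arrays")
  rowMeans(v)
}

#' Fit a global linear normalization model for one array
#'
#' Ordinary least squares of the array's values `y` on the mean reference
#' `x`.
#'
#' @param y numeric vector, one array's log2 signals.
#' @param x numeric vector, the mean reference (same probes, same order).
#' @param arrayId optional id stored in the model.
#' @return A [NormalizationModel-class] with `method = "linear"`.
#' @export
fitLinearNorm <- function(y, x, arrayId = "") {
  if (length(y) != length(x)) stop("y and x must have equal length")
  if (length(x) < 3L) stop("linear fit needs at least 3 probes")
  if (stats::var(x) == 0) stop("zero variance in the reference x")
  xm <- mean(x); ym <- mean(y)
  beta <- sum((x - xm) * (y - ym)) / sum((x - xm)^2)
  alpha <- ym - beta * xm
  new("NormalizationModel", method = "linear", arrayId = arrayId,
      intercept = alpha, slope = beta)
}

#' Apply a fitted linear normalization
#'
#' Subtracts the fitted systematic deviation from the identity line:
#' corrected `y = y - ((alpha + beta * x) - x)`.
#'
#' @param y the array's values.
#' @param model a linear [NormalizationModel-class].
#' @param x the reference the model was fitted against.
#' @return corrected numeric vector.
#' @export
applyLinearNorm <- function(y, model, x) {
  stopifnot(model@method == "linear", length(y) == length(x))
  y - ((model@intercept + model@slope * x) - x)
}

# Tricube kernel on |u| <= 1.
.tricube <- function(u) {
  w <- (1 - pmin(abs(u), 1)^3)^3
  w[abs(u) >= 1] <- 0
  w
}

#' Fit a segmented locally-linear (LOESS) normalization model
#'
#' A locally-weighted linear smooth of `y` on the mean reference `x`. The
#' neighbourhood scale is `diff(range(x)) / segments` — i.e. `segments`
#' equal divisions of the reference range set the smoothing bandwidth — with
#' a tricube weight kernel. The smooth is fitted at `nGrid` points spanning
#' the observed range and evaluated elsewhere by linear interpolation, so
#' the correction is continuous in `x`. Neighbourhoods holding fewer than
#' `minPoints` probes are widened with a warning.
#'
#' @inheritParams fitLinearNorm
#' @param segments number of equal divisions of the range of `x` fixing the
#'   smoothing scale (default 10).
#' @param nGrid number of fitted curve points.
#' @param minPoints minimum probes per neighbourhood before widening.
#' @return A [NormalizationModel-class] with `method = "loess"` and a
#'   `(x, fitted)` lookup curve.
#' @export
fitLoessNorm <- function(y, x, segments = 10L, arrayId = "",
                         nGrid = 101L, minPoints = 10L) {
  if (length(y) != length(x)) stop("y and x must have equal length")
  if (length(x) < 10L * segments)
    stop("loess fit needs at least 10 probes per segment (",
         10L * segments, ")")
  r <- range(x)
  if (diff(r) == 0) stop("zero variance in the reference x")
  h0 <- diff(r) / segments
  grid <- seq(r[1L], r[2L], length.out = nGrid)
  widened <- FALSE
  fitted <- vapply(grid, function(x0) {
    h <- h0
    w <- .tricube((x - x0) / h)
    while (sum(w > 0) < minPoints) {
      h <- 1.5 * h
      w <- .tricube((x - x0) / h)
      widened <<- TRUE
    }
    sw <- sum(w)
    xm <- sum(w * x) / sw
    ym <- sum(w * y) / sw
    sxx <- sum(w * (x - xm)^2)
    b <- if (sxx > .Machine$double.eps * sw) sum(w * (x - xm) * (y - ym)) / sxx
         else 0
    ym + b * (x0 - xm)
  }, numeric(1))
  if (widened)
    warning("sparse neighbourhood(s) in loess fit for array '", arrayId,
            "': bandwidth widened")
  new("NormalizationModel", method = "loess", arrayId = arrayId,
      curve = data.frame(x = grid, fitted = fitted))
}

#' Apply a fitted LOESS normalization
#'
#' Evaluates the fitted smooth `f` at each probe's reference value by
#' linear interpolation (constant beyond the fitted range) and subtracts
#' the deviation from the identity line: corrected `y = y - (f(x) - x)`.
#'
#' @param y the array's values.
#' @param model a loess [NormalizationModel-class].
#' @param x the reference the model was fitted against.
#' @return corrected numeric vector.
#' @export
applyLoessNorm <- function(y, model, x) {
  stopifnot(model@method == "loess", length(y) == length(x))
  f <- stats::approx(model@curve$x, model@curve$fitted, xout = x,
                     rule = 2)$y
  y - (f - x)
}

#' Quantile-normalize a probe-by-array matrix
#'
#' Replaces each array's sorted values by the across-array mean of the
#' values at that rank (ties take the average rank, interpolating the
#' template at half-ranks), so that every column has identical sorted
#' values afterwards.
#'
#' @param m a [ChannelMatrix-class] or numeric matrix with `>= 2` columns.
#' @return object of the same kind as the input with normalized values;
#'   for a `ChannelMatrix`, the quantile template is stored in
#'   `metadata(...)$normalizationModels`.
#' @export
quantileNormalize <- function(m) {
  v <- .signalOf(m)
  if (ncol(v) < 2L) stop("quantile normalization needs at least 2 arrays")
  sorted <- apply(v, 2L, sort)
  template <- rowMeans(sorted)
  ranks <- apply(v, 2L, rank, ties.method = "average")
  out <- apply(ranks, 2L, function(r)
    stats::approx(seq_along(template), template, xout = r)$y)
  dimnames(out) <- dimnames(v)
  if (is(m, "ChannelMatrix")) {
    res <- ChannelMatrix(out, channel = channelName(m),
                         isNegativeControl = isNegativeControl(m),
                         scale = metadata(m)$scale)
    metadata(res)$normalization <- "quantile"
    metadata(res)$normalizationModels <-
      list(new("NormalizationModel", method = "quantile",
               template = template))
    res
  } else out
}

#' Normalize every array against the mean reference
#'
#' Orchestrates one of the three normalization methods over a full matrix:
#' global linear regression to the mean reference, segmented locally-linear
#' (LOESS) regression to the mean reference, or quantile normalization. The
#' reference is computed once from the input matrix and held fixed while
#' each array is corrected; optionally each array can be excluded from its
#' own reference (`leaveOneOut`).
#'
#' @param m a [ChannelMatrix-class] or numeric probe-by-array matrix.
#' @param method `"loess"` (default), `"linear"` or `"quantile"`.
#' @param segments smoothing scale for the loess method (equal divisions of
#'   the reference range).
#' @param leaveOneOut exclude each array from its own mean reference.
#' @return object of the same kind as the input, with per-array fitted
#'   models in `metadata(...)$normalizationModels` for a `ChannelMatrix`.
#' @examples
#' v <- matrix(rnorm(400, 8), 100, 4,
#'             dimnames = list(sprintf("p%03d", 1:100), paste0("a", 1:4)))
#' norm <- normalizeToReference(v, method = "linear")
#' @export
normalizeToReference <- function(m, method = c("loess", "linear", "quantile"),
                                 segments = 10L, leaveOneOut = FALSE) {
  method <- match.arg(method)
  if (method == "quantile") return(quantileNormalize(m))
  v <- .signalOf(m)
  if (ncol(v) < 2L) stop("normalization needs at least 2 arrays")
  x0 <- rowMeans(v)
  out <- v
  models <- vector("list", ncol(v))
  names(models) <- colnames(v)
  for (a in seq_len(ncol(v))) {
    x <- if (leaveOneOut) rowMeans(v[, -a, drop = FALSE]) else x0
    y <- v[, a]
    id <- colnames(v)[a]
    model <- if (method == "linear") fitLinearNorm(y, x, arrayId = id)
             else fitLoessNorm(y, x, segments = segments, arrayId = id)
    out[, a] <- if (method == "linear") applyLinearNorm(y, model, x)
                else applyLoessNorm(y, model, x)
    models[[a]] <- model
  }
  if (is(m, "ChannelMatrix")) {
    res <- ChannelMatrix(out, channel = channelName(m),
                         isNegativeControl = isNegativeControl(m),
                         scale = metadata(m)$scale)
    metadata(res)$normalization <- method
    metadata(res)$normalizationModels <- models
    res
  } else out
}

#' Dump fitted normalization models as a data.frame
#'
#' @param models list of [NormalizationModel-class] objects (as stored in
#'   `metadata(...)$normalizationModels`).
#' @return data.frame suitable for writing as TSV: one row per array for
#'   the linear method (intercept, slope), one row per fitted curve point
#'   for loess.
#' @export
modelTable <- function(models) {
  stopifnot(length(models) >= 1L)
  method <- models[[1L]]@method
  switch(method,
    linear = do.call(rbind, lapply(models, function(md)
      data.frame(arrayId = md@arrayId, intercept = md@intercept,
                 slope = md@slope))),
    loess = do.call(rbind, lapply(models, function(md)
      data.frame(arrayId = md@arrayId, x = md@curve$x,
                 fitted = md@curve$fitted))),
    quantile = data.frame(rank = seq_along(models[[1L]]@template),
                          template = models[[1L]]@template))
}
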