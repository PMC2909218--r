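#' Strip plot of one MDS dimension by group
#'
#' Plots the MDS score of every array along the y axis for the requested
#' dimension(s), one coloured strip per group; a small seeded uniform
#' x-axis jitter separates overlapping points.
#'
#' @param x an [MDSResult-class].
#' @param dims dimensions to plot (default up to the selected k).
#' @param groupBy name of an annotation column used to colour points, or a
#'   vector of group labels.
#' @param jitterSeed seed for the x jitter (deterministic plots).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the plotted data.frame.
#' @export
plotDimensions <- function(x, dims = NULL, groupBy = NULL,
                           jitterSeed = 1L, ...) {
  pts <- mdsPoints(x)
  if (is.null(dims)) dims <- seq_len(min(selectedK(x), ncol(pts)))
  dims <- dims[dims <= ncol(pts)]
  grp <- if (is.null(groupBy)) factor(rep("all", nrow(pts)))
  else if (is.character(groupBy) && length(groupBy) == 1L)
    factor(x@annotations[[groupBy]])
  else factor(groupBy)
  set.seed(jitterSeed)
  df <- do.call(rbind, lapply(dims, function(d)
    data.frame(dim = d, score = pts[, d], group = grp,
               xpos = d + stats::runif(nrow(pts), -0.3, 0.3))))
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op))
  graphics::plot(df$xpos, df$score, col = as.integer(df$group),
                 pch = 19, xaxt = "n", xlab = "dimension",
                 ylab = "MDS score", ...)
  graphics::axis(1, at = dims)
  if (nlevels(grp) > 1L)
    graphics::legend("topright", legend = levels(grp),
                     col = seq_len(nlevels(grp)), pch = 19, bty = "n")
  invisible(df)
}

#' Eigenvalue and goodness-of-fit plots
#'
#' @param x an [MDSResult-class].
#' @param kMax how many leading dimensions to show.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the goodness-of-fit curve.
#' @export
plotGoodnessOfFit <- function(x, kMax = 20L, ...) {
  pk <- goodnessCurve(x)
  k <- seq_len(min(kMax, length(pk)))
  graphics::plot(k, pk[k], type = "b", pch = 19, ylim = c(0, 1),
                 xlab = "dimensions k", ylab = expression(P[k]), ...)
  graphics::abline(h = x@cutoff, lty = 2)
  graphics::abline(v = selectedK(x), lty = 3)
  invisible(pk)
}

#' Plot an expressed-gene call curve
#'
#' @param x a [CallCurve-class] (or a list of them, overlaid).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `NULL`.
#' @export
plotCallCurve <- function(x, ...) {
  curves <- if (is(x, "CallCurve")) list(x) else x
  graphics::plot(callThresholds(curves[[1L]]),
                 100 * fractionOn(curves[[1L]]), type = "b", pch = 19,
                 ylim = c(0, 100),
                 xlab = "threshold above background (log2 units)",
                 ylab = "% probes on", ...)
  if (length(curves) > 1L)
    for (i in seq_along(curves)[-1L])
      graphics::lines(callThresholds(curves[[i]]),
                      100 * fractionOn(curves[[i]]), type = "b",
                      pch = 19, col = i)
  invisible(NULL)
}

#' Histogram of the pooled background distribution
#'
#' @param x a [BackgroundModel-class].
#' @param ... passed to [graphics::hist()].
#' @return invisibly, the histogram object.
#' @export
plotBackgroundDistribution <- function(x, ...) {
  invisible(graphics::hist(pooledBackground(x), breaks = 30,
                           main = "negative-control background",
                           xlab = "log2 signal", ...))
}
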