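#' Dependence of the per-probe SD on the per-probe mean
#'
#' For every probe, computes its mean and sample SD across arrays and
#' regresses SD on mean by ordinary least squares. On raw-scale data the
#' SD grows with the mean; the log2 transform, and then normalization,
#' progressively flatten this dependence.
#'
#' @param m a [ChannelMatrix-class] or numeric probe-by-array matrix with
#'   at least 3 arrays.
#' @param excludeControls drop the negative-control row(s) first (only for
#'   a `ChannelMatrix`).
#' @return list with `slope`, `r.squared`, `slope.se` and the per-probe
#'   `means`/`sds` used.
#' @export
sdVsMean <- function(m, excludeControls = TRUE) {
  v <- .signalOf(m)
  if (is(m, "ChannelMatrix") && excludeControls)
    v <- v[!isNegativeControl(m), , drop = FALSE]
  if (ncol(v) < 3L) stop("sd-vs-mean needs at least 3 arrays")
  means <- rowMeans(v)
  sds <- .rowSds(v)
  fit <- stats::lm(sds ~ means)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       r.squared = sm$r.squared,
       slope.se = sm$coefficients[2L, 2L],
       means = means, sds = sds)
}

# Sample SD per row (n-1 denominator), two-pass for accuracy.
.rowSds <- function(v) {
  n <- ncol(v)
  mu <- rowMeans(v)
  sqrt(rowSums((v - mu)^2) / (n - 1L))
}

# Sample covariance between matching rows of two matrices.
.rowCovs <- function(a, b) {
  n <- ncol(a)
  rowSums((a - rowMeans(a)) * (b - rowMeans(b))) / (n - 1L)
}

#' Per-probe normality screen
#'
#' Applies the Shapiro-Wilk test to every probe's values across arrays and
#' reports the fraction of probes whose distribution is not significantly
#' non-normal (p > `alpha`). The raw (uncorrected) fraction is the primary
#' statistic; a Benjamini-Hochberg-adjusted fraction is reported alongside
#' as a multiplicity-aware companion.
#'
#' @inheritParams sdVsMean
#' @param alpha significance level (default 0.05).
#' @return list with `fraction` (raw pass fraction at p > alpha),
#'   `fractionBH` (pass fraction on BH-adjusted p-values) and `pValues`.
#' @export
normalityScreen <- function(m, alpha = 0.05, excludeControls = TRUE) {
  v <- .signalOf(m)
  if (is(m, "ChannelMatrix") && excludeControls)
    v <- v[!isNegativeControl(m), , drop = FALSE]
  if (ncol(v) < 3L)
    stop("normality screen needs at least 3 arrays")
  if (ncol(v) > 5000L)
    stop("Shapiro-Wilk supports at most 5000 observations per probe")
  p <- apply(v, 1L, function(row) stats::shapiro.test(row)$p.value)
  list(fraction = mean(p > alpha),
       fractionBH = mean(stats::p.adjust(p, "BH") > alpha),
       pValues = p)
}

#' Covariance-corrected SD of the difference of two channels
#'
#' The SD of the per-probe difference (log-ratio) between the experimental
#' and reference channels, `sqrt(sdE^2 + sdR^2 - 2 * cov)`. Taking ratios
#' reduces variance only when the between-channel covariance is large
#' relative to the channel variances.
#'
#' @param sdE SD of the experimental (Cy5) channel.
#' @param sdR SD of the reference (Cy3) channel.
#' @param cov covariance between the channels; must satisfy
#'   `cov^2 <= sdE^2 * sdR^2`.
#' @param tol tolerance below which a negative radicand is treated as
#'   rounding error and clamped to zero (with a warning).
#' @return non-negative SD of the difference.
#' @examples
#' sdOfDifference(0.52, 0.24, 0.09)  # ~0.38
#' sdOfDifference(0.56, 0.31, 0.11)  # ~0.44
#' @export
sdOfDifference <- function(sdE, sdR, cov, tol = 1e-8) {
  if (cov^2 > sdE^2 * sdR^2 + tol)
    stop("invalid covariance: cov^2 exceeds sdE^2 * sdR^2")
  rad <- sdE^2 + sdR^2 - 2 * cov
  if (rad < 0) {
    if (rad < -tol)
      stop("negative variance of the difference beyond tolerance")
    warning("tiny negative radicand clamped to zero")
    rad <- 0
  }
  sqrt(rad)
}

#' Per-probe and summary variance statistics for a channel pair
#'
#' Computes, for every probe across arrays: mean and sample SD in each
#' channel, the sample covariance and the Pearson correlation between the
#' channels. Summary statistics are unweighted means over probes, plus the
#' covariance-corrected SD of the channel difference ([sdOfDifference()]
#' applied to the summary averages) and percentiles of the genewise SDs.
#'
#' Note that the ratio of *averaged* covariance to *averaged* SDs is not
#' the average per-probe correlation — averaging does not commute with the
#' ratio — so both the per-probe correlations and their mean are exposed.
#'
#' @param m5 Cy5 (experimental) [ChannelMatrix-class] or matrix.
#' @param m3 Cy3 (reference) matrix with identical probes and arrays.
#' @param probs percentiles of the genewise SD to report.
#' @return A [VarianceReport-class].
#' @export
channelStats <- function(m5, m3, probs = c(0.5, 0.95)) {
  v5 <- .signalOf(m5); v3 <- .signalOf(m3)
  if (!identical(dim(v5), dim(v3)) ||
      !identical(rownames(v5), rownames(v3)) ||
      !identical(colnames(v5), colnames(v3)))
    stop("Cy5 and Cy3 matrices must match in probes and arrays")
  if (ncol(v5) < 2L) stop("channel statistics need at least 2 arrays")
  sd5 <- .rowSds(v5); sd3 <- .rowSds(v3)
  cv <- .rowCovs(v5, v3)
  cr <- cv / (sd5 * sd3)
  cr[!is.finite(cr)] <- NA_real_
  ps <- data.frame(probe = rownames(v5),
                   meanCy5 = rowMeans(v5), meanCy3 = rowMeans(v3),
                   sdCy5 = sd5, sdCy3 = sd3,
                   covariance = cv, correlation = cr,
                   row.names = NULL, stringsAsFactors = FALSE)
  qs5 <- stats::quantile(sd5, probs)
  qs3 <- stats::quantile(sd3, probs)
  # Eq-1 on the summary averages; because averaging does not commute with
  # products, mean(cov) may slightly exceed mean(sd5)*mean(sd3) for
  # near-perfectly correlated channels, so the radicand is clamped at 0.
  radSummary <- mean(sd5)^2 + mean(sd3)^2 - 2 * mean(cv)
  summary <- list(
    meanSdCy5 = mean(sd5), meanSdCy3 = mean(sd3),
    meanCov = mean(cv), meanCor = mean(cr, na.rm = TRUE),
    sdDifference = sqrt(max(radSummary, 0)),
    sdCy5Percentiles = qs5, sdCy3Percentiles = qs3
  )
  new("VarianceReport", probeStats = ps, summary = summary,
      nArrays = ncol(v5))
}

#' Write a variance report as TSV
#'
#' One row per probe plus a trailing `# summary:` stanza of key-value
#' comment lines.
#'
#' @param report a [VarianceReport-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeVarianceReport <- function(report, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  ps <- probeStats(report)
  writeLines(paste(names(ps), collapse = "\t"), con)
  utils::write.table(ps, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  s <- reportSummary(report)
  writeLines("# summary:", con)
  for (nm in c("meanSdCy5", "meanSdCy3", "meanCov", "meanCor",
               "sdDifference"))
    writeLines(sprintf("# %s\t%.6f", nm, s[[nm]]), con)
  invisible(path)
}
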