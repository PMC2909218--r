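#' Configure the synthetic two-colour array generator
#'
#' Builds a [SimConfig-class] describing a synthetic experiment with the
#' statistical structure of a reference-design two-colour study: every
#' array hybridises the same reference sample in the Cy3 channel and an
#' experimental sample in the Cy5 channel. Probe-level log2 signals are
#' probe mean + array bias + Gaussian noise; the two channels' noise is
#' drawn jointly with a configurable covariance; a subset of probes is
#' spotted in replicate and shares one per-array value plus independent
#' within-array noise; a negative-control probe is spotted many times and
#' drawn around the background level; non-expressed probes sit at
#' background. Signals are exponentiated (2^x) into Feature Extraction
#' files readable by [readFeatureExtraction()].
#'
#' Defaults emulate the study conditions of a 4 x 44K human whole-genome
#' design at desk scale: 2,000 unique probes (41,001 at `fullScale`), 263
#' of them replicated 10 times, a negative-control probe present 153
#' times, genewise noise SD 0.24 (Cy3) and 0.52 (Cy5) with covariance
#' 0.09, within-array replicate SD 0.16/0.20 with covariance 0.02, a
#' background at log2(60), and per-array linear/nonlinear biases (offsets
#' up to +/-0.5 log2 units, slopes 0.9-1.1, mild curvature).
#'
#' @param nProbes number of unique probes (default 2000; 41001 when
#'   `fullScale = TRUE`).
#' @param nReplicateProbes how many probes are spotted `replicateCount`
#'   times (default 263 x 10).
#' @param replicateCount features per replicated probe.
#' @param negativeControlCount features of the negative-control probe.
#' @param nArrays number of arrays.
#' @param meanLog2,probeSd centre and spread of true expressed-probe means
#'   (log2 units).
#' @param noiseSdCy3,noiseSdCy5,channelCov between-array noise SDs per
#'   channel and their covariance (log2 units).
#' @param intraSdCy3,intraSdCy5,intraCov within-array replicate noise SDs
#'   and covariance.
#' @param offsetRange per-array additive offset drawn uniformly from
#'   `[-offsetRange, offsetRange]`.
#' @param slopeRange per-array multiplicative slope drawn uniformly from
#'   `slopeRange` (length-2).
#' @param curvatureRange per-array quadratic curvature drawn uniformly from
#'   `[-curvatureRange, curvatureRange]`.
#' @param biasCenter log2 pivot about which array biases act (defaults to
#'   `meanLog2`).
#' @param expressedFraction fraction of probes truly expressed; the rest
#'   sit at background.
#' @param stimulatedFraction,stimulationEffect fraction of expressed probes
#'   responding in stimulated arrays, and the Cy5 log2 effect size. When
#'   positive, every second array is flagged stimulated.
#' @param backgroundLog2,backgroundSd background level (default log2(60))
#'   and the SD of background draws.
#' @param groupLabels optional character vector, one class label per array
#'   (e.g. cell type); each class gets its own signature of
#'   `groupProbeFraction` expressed probes shifted by `groupEffect` in Cy5.
#' @param groupEffect,groupProbeFraction class-signature effect size (log2)
#'   and fraction of probes per signature.
#' @param negativeControlProbe probe name of the negative control.
#' @param seed integer seed; identical config and seed give byte-identical
#'   files.
#' @param fullScale use the full 41,001-probe layout.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nProbes = 200, nReplicateProbes = 10,
#'                  negativeControlCount = 20, nArrays = 4, seed = 7)
#' cfg
#' @export
simConfig <- function(nProbes = 2000L,
                      nReplicateProbes = 263L,
                      replicateCount = 10L,
                      negativeControlCount = 153L,
                      nArrays = 10L,
                      meanLog2 = 8.5,
                      probeSd = 2.0,
                      noiseSdCy3 = 0.24,
                      noiseSdCy5 = 0.52,
                      channelCov = 0.09,
                      intraSdCy3 = 0.16,
                      intraSdCy5 = 0.20,
                      intraCov = 0.02,
                      offsetRange = 0.5,
                      slopeRange = c(0.9, 1.1),
                      curvatureRange = 0.02,
                      biasCenter = meanLog2,
                      expressedFraction = 0.70,
                      stimulatedFraction = 0,
                      stimulationEffect = 2.0,
                      backgroundLog2 = log2(60),
                      backgroundSd = 0.25,
                      groupLabels = character(0),
                      groupEffect = 1.5,
                      groupProbeFraction = 0.05,
                      negativeControlProbe = "(-)3xSLv1",
                      seed = 1L,
                      fullScale = FALSE) {
  if (fullScale) nProbes <- 41001L
  new("SimConfig",
      nProbes = as.integer(nProbes),
      nReplicateProbes = as.integer(nReplicateProbes),
      replicateCount = as.integer(replicateCount),
      negativeControlCount = as.integer(negativeControlCount),
      nArrays = as.integer(nArrays),
      meanLog2 = meanLog2, probeSd = probeSd,
      noiseSdCy3 = noiseSdCy3, noiseSdCy5 = noiseSdCy5,
      channelCov = channelCov,
      intraSdCy3 = intraSdCy3, intraSdCy5 = intraSdCy5, intraCov = intraCov,
      offsetRange = offsetRange, slopeRange = slopeRange,
      curvatureRange = curvatureRange, biasCenter = biasCenter,
      expressedFraction = expressedFraction,
      stimulatedFraction = stimulatedFraction,
      stimulationEffect = stimulationEffect,
      backgroundLog2 = backgroundLog2, backgroundSd = backgroundSd,
      groupLabels = as.character(groupLabels),
      groupEffect = groupEffect, groupProbeFraction = groupProbeFraction,
      negativeControlProbe = negativeControlProbe,
      seed = as.integer(seed))
}

# Expressed probes sit at least this many log2 units above background so
# that "expressed" is a well-separated truth label (see the vignette).
.EXPRESSED_MARGIN <- 1.2

# Joint (cy3, cy5) Gaussian noise with the given SDs and covariance,
# degenerate-safe (zero SDs allowed).
.bivariateNoise <- function(n, sd3, sd5, cov) {
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  e3 <- sd3 * z1
  if (sd3 > 0) {
    a <- cov / sd3
    b <- sqrt(max(sd5^2 - a^2, 0))
    e5 <- a * z1 + b * z2
  } else {
    e5 <- sd5 * z2
  }
  cbind(cy3 = e3, cy5 = e5)
}

# Array bias curve acting on a true log2 value.
.biasCurve <- function(x, offset, slope, curvature, center) {
  z <- x - center
  x + offset + (slope - 1) * z + curvature * z^2
}

# Truncated normal above `lower` via inverse-CDF sampling.
.rtruncnorm <- function(n, mean, sd, lower) {
  if (sd <= 0) return(rep(max(mean, lower), n))
  plo <- stats::pnorm(lower, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (1 - plo), mean, sd)
}

.writeFEFile <- function(path, featureNum, probeName, controlType, g, r,
                         arrayId) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    "TYPE\ttext\ttext",
    "FEPARAMS\tProtocol_Name\tScan_ArrayId",
    paste("DATA\tSyntheticTwoColour", arrayId, sep = "\t"),
    "*",
    "TYPE\tinteger\ttext\tinteger\tfloat\tfloat",
    "FEATURES\tFeatureNum\tProbeName\tControlType\tgMedianSignal\trMedianSignal"
  ), con)
  writeLines(sprintf("DATA\t%d\t%s\t%d\t%.12g\t%.12g",
                     featureNum, probeName, controlType, g, r), con)
  invisible(path)
}

#' Generate a synthetic dataset of FE files with a known truth table
#'
#' Draws probe means, per-array biases and noise as configured (see
#' [simConfig()]), writes one Feature Extraction file per array plus truth
#' tables into `dir`, and returns the truth in memory. The same
#' configuration and seed always produce byte-identical files.
#'
#' @param cfg a [SimConfig-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, a list with `files` (FE file paths), `truth` (list:
#'   `probes` data.frame, `arrays` data.frame, `cy5Truth` probe-by-array
#'   matrix of true Cy5 log2 means before bias and noise, `cy3Truth`
#'   per-probe true Cy3 log2 means) and `dir`.
#' @examples
#' cfg <- simConfig(nProbes = 100, nReplicateProbes = 5,
#'                  negativeControlCount = 10, nArrays = 3, seed = 11)
#' d <- generateDataset(cfg, dir = tempfile())
#' length(d$files)
#' @export
generateDataset <- function(cfg, dir) {
  validObject(cfg)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(cfg@seed)

  P <- cfg@nProbes
  nA <- cfg@nArrays
  probeId <- sprintf("P%06d", seq_len(P))
  replicated <- sort(sample.int(P, cfg@nReplicateProbes))
  isRep <- seq_len(P) %in% replicated
  nExpr <- round(cfg@expressedFraction * P)
  expressedIdx <- sort(sample.int(P, nExpr))
  expressed <- seq_len(P) %in% expressedIdx

  mu <- rep(cfg@backgroundLog2, P)
  mu[expressed] <- .rtruncnorm(nExpr, cfg@meanLog2, cfg@probeSd,
                               cfg@backgroundLog2 + .EXPRESSED_MARGIN)

  arrayIdv <- sprintf("array%02d", seq_len(nA))
  groups <- if (length(cfg@groupLabels)) cfg@groupLabels
            else rep("A", nA)
  stimulated <- if (cfg@stimulatedFraction > 0)
    seq_len(nA) %% 2L == 0L else rep(FALSE, nA)
  offsets <- stats::runif(nA, -cfg@offsetRange, cfg@offsetRange)
  slopes <- stats::runif(nA, cfg@slopeRange[1], cfg@slopeRange[2])
  curvatures <- stats::runif(nA, -cfg@curvatureRange, cfg@curvatureRange)

  # Class signatures: a disjoint-as-possible set of expressed probes per
  # group, shifted in the Cy5 channel of that group's arrays.
  sigSize <- round(cfg@groupProbeFraction * P)
  signatures <- list()
  pool <- expressedIdx
  for (gl in unique(groups)) {
    take <- sample(pool, min(sigSize, length(pool)))
    signatures[[gl]] <- take
    pool <- setdiff(pool, take)
    if (length(pool) < sigSize) pool <- expressedIdx
  }
  stimProbes <- if (cfg@stimulatedFraction > 0)
    sample(expressedIdx, round(cfg@stimulatedFraction * nExpr))
  else integer(0)

  # True Cy5 means per probe per array (biology, before bias and noise).
  cy5Truth <- matrix(mu, P, nA, dimnames = list(probeId, arrayIdv))
  for (a in seq_len(nA)) {
    sig <- signatures[[groups[a]]]
    cy5Truth[sig, a] <- cy5Truth[sig, a] + cfg@groupEffect
    if (stimulated[a])
      cy5Truth[stimProbes, a] <- cy5Truth[stimProbes, a] +
        cfg@stimulationEffect
  }

  # Feature layout, shared by all arrays: singles, replicate blocks,
  # negative controls, in a shuffled order.
  featProbe <- c(probeId[!isRep],
                 rep(probeId[isRep], each = cfg@replicateCount),
                 rep(cfg@negativeControlProbe, cfg@negativeControlCount))
  featProbeIdx <- c(which(!isRep),
                    rep(which(isRep), each = cfg@replicateCount),
                    rep(NA_integer_, cfg@negativeControlCount))
  featCtrl <- c(rep(0L, sum(!isRep) + sum(isRep) * cfg@replicateCount),
                rep(-1L, cfg@negativeControlCount))
  ord <- sample.int(length(featProbe))
  featProbe <- featProbe[ord]; featProbeIdx <- featProbeIdx[ord]
  featCtrl <- featCtrl[ord]
  nFeat <- length(featProbe)

  files <- character(nA)
  for (a in seq_len(nA)) {
    noise <- .bivariateNoise(P, cfg@noiseSdCy3, cfg@noiseSdCy5,
                             cfg@channelCov)
    # Background features fluctuate around the (bias-shifted) background
    # level rather than carrying channel noise. The array bias acts on the
    # true level; noise is added afterwards, so the bias curve shifts
    # probes without rescaling their noise.
    bg3 <- stats::rnorm(P, 0, cfg@backgroundSd)
    bg5 <- stats::rnorm(P, 0, cfg@backgroundSd)
    biasBg <- .biasCurve(cfg@backgroundLog2, offsets[a], slopes[a],
                         curvatures[a], cfg@biasCenter)
    v3 <- ifelse(expressed,
                 .biasCurve(mu, offsets[a], slopes[a], curvatures[a],
                            cfg@biasCenter) + noise[, "cy3"],
                 biasBg + bg3)
    v5 <- ifelse(expressed,
                 .biasCurve(cy5Truth[, a], offsets[a], slopes[a],
                            curvatures[a], cfg@biasCenter) + noise[, "cy5"],
                 biasBg + bg5)

    isCtrlFeat <- is.na(featProbeIdx)
    f3 <- numeric(nFeat); f5 <- numeric(nFeat)
    f3[!isCtrlFeat] <- v3[featProbeIdx[!isCtrlFeat]]
    f5[!isCtrlFeat] <- v5[featProbeIdx[!isCtrlFeat]]
    f3[isCtrlFeat] <- biasBg + stats::rnorm(sum(isCtrlFeat), 0,
                                            cfg@backgroundSd)
    f5[isCtrlFeat] <- biasBg + stats::rnorm(sum(isCtrlFeat), 0,
                                            cfg@backgroundSd)

    # Independent within-array noise for every copy of a replicated probe.
    isRepFeat <- !isCtrlFeat & featProbe %in% probeId[isRep]
    if (any(isRepFeat)) {
      intra <- .bivariateNoise(sum(isRepFeat), cfg@intraSdCy3,
                               cfg@intraSdCy5, cfg@intraCov)
      f3[isRepFeat] <- f3[isRepFeat] + intra[, "cy3"]
      f5[isRepFeat] <- f5[isRepFeat] + intra[, "cy5"]
    }

    files[a] <- file.path(dir, paste0(arrayIdv[a], ".txt"))
    .writeFEFile(files[a], seq_len(nFeat), featProbe, featCtrl,
                 2^f3, 2^f5, arrayIdv[a])
  }

  probes <- data.frame(
    probeId = probeId,
    expressed = expressed,
    isReplicated = isRep,
    muLog2 = mu,
    stringsAsFactors = FALSE
  )
  arrays <- data.frame(
    arrayId = arrayIdv,
    offset = offsets, slope = slopes, curvature = curvatures,
    group = groups, stimulated = stimulated,
    stringsAsFactors = FALSE
  )
  utils::write.table(probes, file.path(dir, "truth_probes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(arrays, file.path(dir, "truth_arrays.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeSignalMatrix(cy5Truth, file.path(dir, "truth_cy5.tsv"))
  truth <- list(probes = probes, arrays = arrays, cy5Truth = cy5Truth,
                cy3Truth = stats::setNames(mu, probeId),
                signatures = signatures, stimProbes = probeId[stimProbes])
  invisible(list(files = files, truth = truth, dir = dir))
}

#' Generate an off-domain (cross-species) control sample
#'
#' Emulates hybridising RNA from a distantly related organism: nearly all
#' probes see only background-level signal, with a small configurable
#' fraction mildly elevated. Used to calibrate the false-positive rate of
#' expressed/not-expressed calling.
#'
#' @param cfg a [SimConfig-class]; layout, background and bias settings are
#'   reused.
#' @param path output FE file path.
#' @param elevatedFraction fraction of probes mildly above background
#'   (default 0.02).
#' @param elevation log2 elevation of those probes (default 1.0).
#' @param seed seed (defaults to the config seed).
#' @param arrayIdLabel array id written into the file.
#' @return Invisibly, a list with `path` and `truth` (data.frame with
#'   `probeId`, `elevated`).
#' @export
generateOffDomainSample <- function(cfg, path,
                                    elevatedFraction = 0.02,
                                    elevation = 1.0,
                                    seed = cfg@seed,
                                    arrayIdLabel = "offdomain01") {
  validObject(cfg)
  stopifnot(elevatedFraction >= 0, elevatedFraction <= 1)
  set.seed(as.integer(seed))
  P <- cfg@nProbes
  probeId <- sprintf("P%06d", seq_len(P))
  replicated <- sort(sample.int(P, cfg@nReplicateProbes))
  isRep <- seq_len(P) %in% replicated
  elevated <- stats::runif(P) < elevatedFraction

  offset <- stats::runif(1, -cfg@offsetRange, cfg@offsetRange)
  slope <- stats::runif(1, cfg@slopeRange[1], cfg@slopeRange[2])
  curvature <- stats::runif(1, -cfg@curvatureRange, cfg@curvatureRange)

  # Bias acts on the true level; noise is added afterwards (same order as
  # in generateDataset).
  base <- .biasCurve(cfg@backgroundLog2 + elevation * elevated,
                     offset, slope, curvature, cfg@biasCenter)
  v3 <- base + stats::rnorm(P, 0, cfg@backgroundSd)
  v5 <- base + stats::rnorm(P, 0, cfg@backgroundSd)

  featProbe <- c(probeId[!isRep],
                 rep(probeId[isRep], each = cfg@replicateCount),
                 rep(cfg@negativeControlProbe, cfg@negativeControlCount))
  featIdx <- c(which(!isRep), rep(which(isRep), each = cfg@replicateCount),
               rep(NA_integer_, cfg@negativeControlCount))
  featCtrl <- c(rep(0L, sum(!isRep) + sum(isRep) * cfg@replicateCount),
                rep(-1L, cfg@negativeControlCount))
  ord <- sample.int(length(featProbe))
  featProbe <- featProbe[ord]; featIdx <- featIdx[ord]
  featCtrl <- featCtrl[ord]

  isCtrl <- is.na(featIdx)
  f3 <- numeric(length(featProbe)); f5 <- numeric(length(featProbe))
  f3[!isCtrl] <- v3[featIdx[!isCtrl]]
  f5[!isCtrl] <- v5[featIdx[!isCtrl]]
  biasBg <- .biasCurve(cfg@backgroundLog2, offset, slope, curvature,
                       cfg@biasCenter)
  f3[isCtrl] <- biasBg + stats::rnorm(sum(isCtrl), 0, cfg@backgroundSd)
  f5[isCtrl] <- biasBg + stats::rnorm(sum(isCtrl), 0, cfg@backgroundSd)
  isRepFeat <- !isCtrl & featProbe %in% probeId[isRep]
  if (any(isRepFeat)) {
    intra <- .bivariateNoise(sum(isRepFeat), cfg@intraSdCy3,
                             cfg@intraSdCy5, cfg@intraCov)
    f3[isRepFeat] <- f3[isRepFeat] + intra[, "cy3"]
    f5[isRepFeat] <- f5[isRepFeat] + intra[, "cy5"]
  }

  if (!dir.exists(dirname(path))) dir.create(dirname(path), recursive = TRUE)
  .writeFEFile(path, seq_along(featProbe), featProbe, featCtrl,
               2^f3, 2^f5, arrayIdLabel)
  invisible(list(path = path,
                 truth = data.frame(probeId = probeId, elevated = elevated,
                                    stringsAsFactors = FALSE),
                 bias = c(offset = offset, slope = slope,
                          curvature = curvature)))
}
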