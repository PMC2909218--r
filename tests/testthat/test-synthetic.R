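noiselessConfig <- function(...) {
  simConfig(noiseSdCy3 = 0, noiseSdCy5 = 0, channelCov = 0,
            intraSdCy3 = 0, intraSdCy5 = 0, intraCov = 0,
            backgroundSd = 0, offsetRange = 0, slopeRange = c(1, 1),
            curvatureRange = 0, ...)
}

test_that("identical config and seed give byte-identical FE files", {
  cfg <- simConfig(nProbes = 150, nReplicateProbes = 8,
                   negativeControlCount = 12, nArrays = 3, seed = 77)
  d1 <- generateDataset(cfg, dir = tempfile())
  d2 <- generateDataset(cfg, dir = tempfile())
  for (i in seq_along(d1$files))
    expect_identical(readLines(d1$files[i]), readLines(d2$files[i]))
})

test_that("with zero noise and identity bias every array equals the truth", {
  cfg <- noiselessConfig(nProbes = 120, nReplicateProbes = 6,
                         negativeControlCount = 10, nArrays = 3, seed = 5)
  d <- generateDataset(cfg, dir = tempfile())
  tabs <- readFeatureExtractionDir(d$dir)
  m3 <- buildChannelMatrix(tabs, "Cy3")
  v <- signalValues(m3)[!isNegativeControl(m3), ]
  truth <- d$truth$probes$muLog2[match(rownames(v), d$truth$probes$probeId)]
  for (a in seq_len(ncol(v)))
    expect_equal(unname(v[, a]), truth, tolerance = 1e-9)
  # Cy5 matches its per-array truth matrix as well
  m5 <- buildChannelMatrix(tabs, "Cy5")
  v5 <- signalValues(m5)[!isNegativeControl(m5), ]
  expect_equal(unname(v5), unname(d$truth$cy5Truth[rownames(v5), ]),
               tolerance = 1e-9)
})

test_that("empirical channel covariance converges to the configured value", {
  cfg <- simConfig(nProbes = 5000, nReplicateProbes = 0,
                   negativeControlCount = 10, nArrays = 12,
                   expressedFraction = 1, offsetRange = 0,
                   slopeRange = c(1, 1), curvatureRange = 0, seed = 9)
  d <- generateDataset(cfg, dir = tempfile())
  tabs <- readFeatureExtractionDir(d$dir)
  v3 <- signalValues(buildChannelMatrix(tabs, "Cy3"))
  v5 <- signalValues(buildChannelMatrix(tabs, "Cy5"))
  keep <- rownames(v3) != "(-)3xSLv1"
  rep <- channelStats(v5[keep, ], v3[keep, ])
  # mean per-probe covariance: SE ~ sd(cov_i)/sqrt(P) ~ 0.0007
  expect_equal(reportSummary(rep)$meanCov, 0.09, tolerance = 0.05)
  expect_lt(abs(reportSummary(rep)$meanCov - 0.09), 0.005)
})

test_that("pre-normalization genewise SD matches the noise + bias oracle", {
  cfg <- simConfig(nProbes = 2000, nReplicateProbes = 0,
                   negativeControlCount = 10, nArrays = 20,
                   expressedFraction = 1, seed = 31)
  d <- generateDataset(cfg, dir = tempfile())
  tabs <- readFeatureExtractionDir(d$dir)
  v3 <- signalValues(buildChannelMatrix(tabs, "Cy3"))
  v3 <- v3[rownames(v3) != "(-)3xSLv1", ]
  mu <- d$truth$probes$muLog2[match(rownames(v3), d$truth$probes$probeId)]
  arr <- d$truth$arrays
  # direct oracle: per-probe SD = noise variance + variance over the drawn
  # array bias curves evaluated at the probe's true mean
  predicted <- vapply(mu, function(m) {
    z <- m - cfg@biasCenter
    biases <- arr$offset + (arr$slope - 1) * z + arr$curvature * z^2
    sqrt(0.24^2 + var(biases))
  }, numeric(1))
  observed <- apply(v3, 1L, sd)
  expect_lt(abs(mean(observed) - mean(predicted)) / mean(predicted), 0.15)
})

test_that("off-domain samples are background-dominated", {
  cfg <- simConfig(nProbes = 2000, nReplicateProbes = 50,
                   negativeControlCount = 100, nArrays = 1, seed = 13)
  off <- generateOffDomainSample(cfg, tempfile(fileext = ".txt"))
  ft <- readFeatureExtraction(off$path)
  cc <- collapseReplicates(ft, "Cy5")
  bg <- fitBackground(ft, channel = "Cy5")
  frac <- mean(cc$values[!cc$isNegativeControl] >
                 backgroundStatistic(bg) + 0.5)
  expect_lt(frac, 0.05)

  # zero elevated fraction: false positives match the Gaussian noise tail
  off0 <- generateOffDomainSample(cfg, tempfile(fileext = ".txt"),
                                  elevatedFraction = 0, seed = 14)
  ft0 <- readFeatureExtraction(off0$path)
  cc0 <- collapseReplicates(ft0, "Cy5")
  bg0 <- fitBackground(ft0, channel = "Cy5")
  x0 <- cc0$values[!cc0$isNegativeControl]
  # oracle against the true (bias-shifted) background, so that background
  # estimation error does not enter
  b <- off0$bias
  z <- cfg@backgroundLog2 - cfg@biasCenter
  trueBg <- cfg@backgroundLog2 + b["offset"] + (b["slope"] - 1) * z +
    b["curvature"] * z^2
  frac0 <- mean(x0 > trueBg + 0.5)
  p <- 1 - pnorm(0.5 / cfg@backgroundSd)
  expect_lt(abs(frac0 - p), 3 * sqrt(p * (1 - p) / length(x0)) + 1e-3)

  # fully elevated: essentially everything is called on
  off1 <- generateOffDomainSample(cfg, tempfile(fileext = ".txt"),
                                  elevatedFraction = 1, elevation = 2,
                                  seed = 15)
  ft1 <- readFeatureExtraction(off1$path)
  cc1 <- collapseReplicates(ft1, "Cy5")
  bg1 <- fitBackground(ft1, channel = "Cy5")
  frac1 <- mean(cc1$values[!cc1$isNegativeControl] >
                  backgroundStatistic(bg1) + 0.5)
  expect_gt(frac1, 0.99)
})

test_that("invalid covariance is rejected before generation", {
  expect_error(simConfig(noiseSdCy3 = 0.1, noiseSdCy5 = 0.1,
                         channelCov = 0.5),
               "covariance")
})
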