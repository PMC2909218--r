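test_that("background statistic is the mean of negative-control signals", {
  ft <- makeFeatureTable(rep("(-)3xSLv1", 153), log2g = rep(5.5, 153),
                         controlType = rep(-1L, 153))
  bg <- fitBackground(ft, channel = "Cy3")
  expect_equal(unname(backgroundStatistic(bg)), 5.5)
  expect_length(pooledBackground(bg), 153)

  ft2 <- makeFeatureTable(c("pA", "(-)3xSLv1", "(-)3xSLv1"),
                          log2g = c(9, 5.8, 6.0),
                          controlType = c(0L, -1L, -1L))
  expect_equal(unname(backgroundStatistic(fitBackground(ft2, "Cy3"))), 5.9)

  ft3 <- makeFeatureTable("pA", log2g = 9)
  expect_error(fitBackground(ft3, channel = "Cy3"), "\\(-\\)3xSLv1")
})

test_that("background recovery on generated arrays matches the truth", {
  cfg <- simConfig(nProbes = 500, nReplicateProbes = 10,
                   negativeControlCount = 153, nArrays = 4, seed = 81)
  d <- generateDataset(cfg, dir = tempfile())
  tabs <- readFeatureExtractionDir(d$dir)
  m5 <- buildChannelMatrix(tabs, "Cy5")
  bg <- fitBackground(m5)
  arr <- d$truth$arrays
  # the true per-array background is the bias curve at backgroundLog2
  z <- cfg@backgroundLog2 - cfg@biasCenter
  expected <- cfg@backgroundLog2 + arr$offset + (arr$slope - 1) * z +
    arr$curvature * z^2
  se <- cfg@backgroundSd / sqrt(cfg@negativeControlCount)
  expect_true(all(abs(backgroundStatistic(bg) - expected) < 5 * se))
})

test_that("call curves are monotone and match a brute-force count", {
  set.seed(82)
  x <- rnorm(500, 7, 1)
  th <- seq(-3, 3, by = 0.25)
  cc <- callExpressed(x, 6.0, thresholds = th)
  f <- fractionOn(cc)
  expect_true(all(diff(f) <= 0))
  for (i in seq_along(th))
    expect_identical(f[i], naiveCallFraction(x, 6.0, th[i]))
  # boundary behaviour
  expect_equal(fractionOn(callExpressed(x, 6.0, thresholds = 1e6)), 0)
  expect_equal(fractionOn(callExpressed(x, 6.0, thresholds = -1e6)), 1)
  # strict inequality: signal exactly at background is "off"
  cc0 <- callExpressed(rep(6.0, 10), 6.0, thresholds = 0)
  expect_equal(fractionOn(cc0), 0)
  expect_error(callExpressed(x, 6.0, thresholds = c(1, 0)), "ascending")
})

test_that("calls on generator truth match binomial predictions", {
  cfg <- simConfig(nProbes = 2000, nReplicateProbes = 50,
                   negativeControlCount = 153, nArrays = 3, seed = 83)
  d <- generateDataset(cfg, dir = tempfile())
  tabs <- readFeatureExtractionDir(d$dir)
  n5 <- suppressWarnings(
    normalizeToReference(buildChannelMatrix(tabs, "Cy5"), "loess"))
  bg <- fitBackground(n5)
  v <- signalValues(n5)[!isNegativeControl(n5), ]
  x <- rowMeans(v)  # average of three samples, as in a triplicate design
  cc <- callExpressed(x, bg, thresholds = 0.5, pooled = TRUE)
  planted <- mean(d$truth$probes$expressed)
  ciHalf <- 3 * sqrt(planted * (1 - planted) / length(x))
  expect_lt(abs(fractionOn(cc) - planted), ciHalf + 0.02)
})

test_that("channel interference is detected only where it is injected", {
  set.seed(84)
  n <- 3000
  # long-tailed stimulation indices so the top-ranked subset spans a range
  d5 <- c(runif(n - 100, 0, 4), runif(100, 4, 8))
  d3 <- rnorm(n, 0, 0.2)
  hot <- d5 > 4
  d3[hot] <- 0.3 * d5[hot] + rnorm(sum(hot), 0, 0.1)
  res <- channelInterference(d5, d3,
                             bins = list(c(2.5, 3), c(3, 4), c(4, Inf)),
                             topN = 50)
  b <- res$bins
  expect_gt(b$correlation[b$lo == 4], 0.6)
  expect_lt(abs(b$correlation[b$lo == 2.5]), 0.25)
  expect_equal(b$slope[b$lo == 4], 0.3, tolerance = 0.35)
  expect_gt(res$top$correlation, 0.5)

  # pure null: no bin shows structure
  d3n <- rnorm(n, 0, 0.2)
  resn <- channelInterference(d5, d3n)
  expect_true(all(abs(resn$bins$correlation) < 0.15))

  # identical channels are perfectly correlated in every bin
  resi <- channelInterference(d5, d5)
  expect_true(all(abs(resi$bins$correlation - 1) < 1e-12))

  # an empty bin reports NA rather than failing
  rese <- channelInterference(d5, d3, bins = list(c(50, 60)))
  expect_true(is.na(rese$bins$correlation))
  expect_error(channelInterference(d5, d3,
                                   bins = list(c(1, 3), c(2, 4))),
               "disjoint")
})
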