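test_that("log2 transform matches the raw signal range arithmetic", {
  expect_equal(log2Transform(60), 5.9069, tolerance = 1e-4)
  expect_equal(log2Transform(200000), 17.6096, tolerance = 1e-4)
  expect_equal(log2Transform(1), 0)
  expect_error(log2Transform(0), "positive")
  expect_error(log2Transform(c(2, -1)), "positive")
})

test_that("replicate collapse averages log2 signals and reports group SDs", {
  ft <- makeFeatureTable(c(rep("pRep", 2), "pSingle"),
                         log2g = c(8, 9, 5))
  cc <- collapseReplicates(ft, "Cy3")
  expect_equal(unname(cc$values["pRep"]), 8.5)
  expect_equal(cc$report$sd[cc$report$probe == "pRep"], sd(c(8, 9)))
  expect_equal(cc$report$sd[cc$report$probe == "pRep"], 0.7071,
               tolerance = 1e-4)

  ft2 <- makeFeatureTable(rep("pRep", 10), log2g = rep(7.25, 10))
  cc2 <- collapseReplicates(ft2, "Cy3")
  expect_equal(unname(cc2$values), 7.25)
  expect_equal(cc2$report$sd, 0)
  expect_equal(cc2$report$count, 10L)
})

test_that("collapse is idempotent and order-independent", {
  set.seed(1)
  probes <- sample(rep(sprintf("p%02d", 1:20), times = sample(1:4, 20, TRUE)))
  ft <- makeFeatureTable(probes, log2g = rnorm(length(probes), 8))
  cc <- collapseReplicates(ft, "Cy3")
  perm <- sample(nrow(featureData(ft)))
  ftp <- new("FeatureTable", arrayId = "t1",
             features = featureData(ft)[perm, ])
  expect_equal(collapseReplicates(ftp, "Cy3")$values, cc$values)
  # collapsing an already-collapsed table changes nothing
  ftc <- makeFeatureTable(names(cc$values), log2g = unname(cc$values))
  expect_equal(collapseReplicates(ftc, "Cy3")$values, cc$values)
  expect_equal(length(cc$values), length(unique(probes)))
})

test_that("other control features are excluded, negative control kept", {
  ft <- makeFeatureTable(c("pA", "corner", "(-)3xSLv1", "(-)3xSLv1"),
                         log2g = c(8, 12, 5.8, 6.0),
                         controlType = c(0L, 1L, -1L, -1L))
  cc <- collapseReplicates(ft, "Cy3")
  expect_setequal(names(cc$values), c("pA", "(-)3xSLv1"))
  expect_equal(unname(cc$values["(-)3xSLv1"]), 5.9)
  expect_identical(cc$isNegativeControl,
                   names(cc$values) == "(-)3xSLv1")
})

test_that("average replicate SD recovers the configured within-array noise", {
  cfg <- simConfig(nProbes = 400, nReplicateProbes = 150,
                   negativeControlCount = 20, nArrays = 1,
                   expressedFraction = 1, seed = 21)
  d <- generateDataset(cfg, dir = tempfile())
  ft <- readFeatureExtraction(d$files[1])
  cc3 <- collapseReplicates(ft, "Cy3")
  cc5 <- collapseReplicates(ft, "Cy5")
  # sample SD of 10 Gaussian draws is biased by the c4 factor ~0.9727
  c4 <- sqrt(2 / 9) * gamma(5) / gamma(4.5)
  expect_equal(cc3$meanReplicateSd, 0.16 * c4, tolerance = 0.08)
  expect_equal(cc5$meanReplicateSd, 0.20 * c4, tolerance = 0.08)
})

test_that("matrix assembly requires a shared probe set", {
  ft1 <- makeFeatureTable(c("pA", "pB"), log2g = c(8, 9), arrayId = "a1")
  ft2 <- makeFeatureTable(c("pA", "pC"), log2g = c(8, 9), arrayId = "a2")
  expect_error(buildChannelMatrix(list(ft1, ft2), "Cy3"),
               "common probe set")
  ft3 <- makeFeatureTable(c("pA", "pB"), log2g = c(7, 10), arrayId = "a2")
  m <- buildChannelMatrix(list(ft1, ft3), "Cy3")
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(probeIds(m), c("pA", "pB"))
})
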