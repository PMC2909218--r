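test_that("mean reference is the per-probe mean across arrays", {
  v <- cbind(a1 = c(6, 8), a2 = c(8, 10))
  rownames(v) <- c("p1", "p2")
  expect_equal(unname(meanReference(v)), c(7, 9))
  big <- randomMatrix(500, 20, seed = 4)
  expect_equal(meanReference(big), apply(big, 1, mean), tolerance = 1e-12)
  m <- big[, 1, drop = FALSE]
  expect_error(meanReference(m), "2 arrays")
})

test_that("linear fit reproduces closed-form OLS", {
  x <- seq(5, 12, length.out = 50)
  m <- fitLinearNorm(x, x)
  expect_equal(m@intercept, 0, tolerance = 1e-12)
  expect_equal(m@slope, 1, tolerance = 1e-12)
  m2 <- fitLinearNorm(x + 0.5, x)
  expect_equal(m2@intercept, 0.5, tolerance = 1e-12)
  expect_equal(m2@slope, 1, tolerance = 1e-12)

  set.seed(8)
  y <- 1.07 * x - 0.4 + rnorm(50, 0, 0.2)
  m3 <- fitLinearNorm(y, x)
  cf <- coef(lm(y ~ x))
  expect_equal(m3@intercept, unname(cf[1]), tolerance = 1e-10)
  expect_equal(m3@slope, unname(cf[2]), tolerance = 1e-10)
  expect_error(fitLinearNorm(y, rep(1, 50)), "zero variance")
})

test_that("linear correction removes the fitted systematic deviation", {
  x <- seq(5, 12, length.out = 200)
  expect_equal(applyLinearNorm(x, fitLinearNorm(x, x), x), x)
  y <- x + 0.5
  expect_equal(applyLinearNorm(y, fitLinearNorm(y, x), x), x,
               tolerance = 1e-12)
  set.seed(3)
  y2 <- 1.1 * x - 0.8 + rnorm(200, 0, 0.1)
  corr <- applyLinearNorm(y2, fitLinearNorm(y2, x), x)
  refit <- coef(lm(corr ~ x))
  expect_equal(unname(refit[2]), 1, tolerance = 1e-10)
  expect_equal(unname(refit[1]), 0, tolerance = 1e-9)
})

test_that("loess correction is identity on already-aligned data", {
  set.seed(2)
  x <- sort(runif(400, 5, 15))
  m <- fitLoessNorm(x, x)
  expect_equal(applyLoessNorm(x, m, x), x, tolerance = 1e-6)
})

test_that("loess correction removes smooth nonlinear bias", {
  set.seed(12)
  x <- sort(runif(2000, 4, 14))
  curv <- 0.01 * (x - mean(x))^2
  y <- x + curv + rnorm(2000, 0, 0.05)
  corr <- applyLoessNorm(y, fitLoessNorm(y, x), x)
  refit <- coef(lm(corr - x ~ x + I((x - mean(x))^2)))
  expect_lt(abs(unname(refit[3])), 0.002)   # curvature gone
  expect_lt(sd(corr - x), sd(y - x))        # closer to the truth
  expect_lt(mean(abs(corr - x)), mean(abs(y - x)))
})

test_that("loess beats no correction on a biased synthetic array", {
  # one array with offset -0.3, slope 0.96 and mild curvature, like a
  # typical miscalibrated array
  set.seed(30)
  truth <- sort(rnorm(1500, 9, 2))
  z <- truth - 9
  y <- truth - 0.3 + (0.96 - 1) * z + 0.015 * z^2 + rnorm(1500, 0, 0.2)
  x <- truth  # reference: noise-free mean of many arrays
  corr <- applyLoessNorm(y, fitLoessNorm(y, x), x)
  expect_lt(mean(abs(corr - truth)), mean(abs(y - truth)))
})

test_that("quantile normalization equalizes column distributions", {
  v <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  rownames(v) <- paste0("p", 1:3)
  q <- quantileNormalize(v)
  expect_equal(unname(q[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(q[, "b"]), c(2.5, 3.5, 4.5))

  same <- randomMatrix(50, 4, seed = 6)
  same[] <- same[, 1]
  expect_equal(quantileNormalize(same), same)

  r <- randomMatrix(300, 6, seed = 16)
  qr <- quantileNormalize(r)
  sorted <- apply(qr, 2, sort)
  for (j in 2:ncol(sorted))
    expect_equal(sorted[, j], sorted[, 1], tolerance = 1e-12)
  # rank order within each array is preserved
  for (j in seq_len(ncol(r)))
    expect_equal(order(qr[, j]), order(r[, j]))
})

test_that("quantile normalization agrees with limma's implementation", {
  skip_if_not_installed("limma")
  r <- randomMatrix(200, 5, seed = 26)
  expect_equal(unname(quantileNormalize(r)),
               unname(limma::normalizeQuantiles(r, ties = TRUE)),
               tolerance = 1e-10)
})

test_that("normalization is near-idempotent on noiseless fixtures", {
  set.seed(40)
  truth <- sort(rnorm(800, 9, 2))
  v <- vapply(1:5, function(a) truth + 0.1 * a - 0.3 +
                ((0.95 + 0.02 * a) - 1) * (truth - 9), numeric(800))
  dimnames(v) <- list(sprintf("p%03d", seq_len(800)), paste0("a", 1:5))
  for (meth in c("linear", "loess", "quantile")) {
    once <- normalizeToReference(v, meth)
    twice <- normalizeToReference(once, meth)
    expect_lt(max(abs(twice - once)), 1e-6)
  }
})

test_that("loess recovers the residual noise scale on synthetic arrays", {
  cfg <- simConfig(nProbes = 1000, nReplicateProbes = 0,
                   negativeControlCount = 10, nArrays = 10,
                   expressedFraction = 1, seed = 55)
  d <- generateDataset(cfg, dir = tempfile())
  v <- signalValues(buildChannelMatrix(readFeatureExtractionDir(d$dir),
                                       "Cy3"))
  v <- v[rownames(v) != "(-)3xSLv1", ]
  nv <- suppressWarnings(normalizeToReference(v, "loess"))
  sds <- apply(nv, 1, sd)
  expect_lt(abs(mean(sds) - 0.24) / 0.24, 0.15)
})

test_that("leave-one-out reference excludes the focal array", {
  v <- randomMatrix(400, 4, seed = 61)
  v[, 1] <- v[, 1] + 2  # gross outlier array
  nIn <- normalizeToReference(v, "linear")
  nOut <- normalizeToReference(v, "linear", leaveOneOut = TRUE)
  expect_false(isTRUE(all.equal(nIn[, 1], nOut[, 1])))
})
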