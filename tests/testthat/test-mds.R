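test_that("distance matrix matches the brute-force definition", {
  v <- cbind(a = c(0, 0), b = c(3, 4))
  rownames(v) <- c("p1", "p2")
  d <- distanceMatrix(v)
  expect_equal(d["a", "b"], 5)
  expect_equal(diag(d), c(a = 0, b = 0))

  same <- randomMatrix(20, 4, seed = 90)
  same[] <- same[, 1]
  expect_true(all(distanceMatrix(same) == 0))

  r <- randomMatrix(50, 10, seed = 91)
  expect_equal(distanceMatrix(r), naiveDistanceMatrix(r),
               tolerance = 1e-10)
  bad <- r; bad[1, 1] <- NA
  expect_error(distanceMatrix(bad), "non-finite")
})

test_that("degenerate configurations give the forced eigenvalue patterns", {
  # three equally spaced collinear points: rank-1 configuration
  pts <- cbind(c(0, 1, 2))
  d <- as.matrix(dist(pts))
  res <- classicalMDS(d)
  ev <- eigenvalues(res)
  expect_gt(ev[1], 0)
  expect_lt(max(abs(ev[2:3])), 1e-10)

  # equilateral triangle with unit side: two equal positive eigenvalues
  tri <- matrix(0, 3, 3); tri[lower.tri(tri)] <- 1
  tri <- tri + t(tri)
  res2 <- classicalMDS(tri)
  ev2 <- eigenvalues(res2)
  expect_equal(ev2[1], ev2[2], tolerance = 1e-10)
  expect_gt(ev2[2], 0)
  expect_lt(abs(ev2[3]), 1e-10)
})

test_that("goodness of fit is the clamped cumulative eigenvalue fraction", {
  expect_equal(goodnessOfFit(c(10, 0, 0), 1), 1.0)
  expect_equal(goodnessOfFit(c(4, 3, 2, 1), 2), 0.7)
  # negative eigenvalues are clamped, not subtracted
  expect_equal(goodnessOfFit(c(4, 3, 2, 1, -2), 2), 0.7)
  expect_error(goodnessOfFit(c(-1, -2), 1), "non-positive")
  expect_error(goodnessOfFit(c(4, 3), 3), "k must lie")

  # regular simplex: equal eigenvalue shares, P_k = k/(n-1)
  n <- 5
  simplex <- matrix(1, n, n) - diag(n)
  res <- classicalMDS(simplex, cutoff = 0.8)
  pk <- goodnessCurve(res)
  expect_equal(pk, (1:(n - 1)) / (n - 1), tolerance = 1e-10)
  expect_equal(pk[n - 1], 1)
})

test_that("full-rank embedding reproduces Euclidean distances", {
  set.seed(92)
  cloud <- matrix(rnorm(30 * 4), 30, 4)
  d <- as.matrix(dist(cloud))
  dimnames(d) <- list(paste0("a", 1:30), paste0("a", 1:30))
  res <- classicalMDS(d)
  rec <- as.matrix(dist(mdsPoints(res)))
  expect_equal(unname(rec), unname(d), tolerance = 1e-8)
  expect_equal(goodnessCurve(res)[29], 1, tolerance = 1e-12)
})

test_that("classical scaling is equivalent to PCA for Euclidean data", {
  v <- randomMatrix(80, 12, seed = 93)
  res <- classicalMDS(distanceMatrix(v))
  pcs <- prcomp(t(v), center = TRUE)$x
  k <- ncol(mdsPoints(res))
  expect_equal(as.matrix(dist(mdsPoints(res))),
               as.matrix(dist(pcs[, seq_len(k)])), tolerance = 1e-8)
  # and agrees with stats::cmdscale as an independent implementation
  ref <- cmdscale(distanceMatrix(v), k = k, eig = TRUE)
  expect_equal(abs(mdsPoints(res)), abs(ref$points), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(eigenvalues(res)[seq_len(k)], ref$eig[seq_len(k)],
               tolerance = 1e-8)
})

test_that("dimension selection takes the smallest k reaching the cutoff", {
  expect_equal(selectDimensions(c(0.5, 0.79, 0.81, 0.9), cutoff = 0.8), 3)
  expect_equal(selectDimensions(c(0.5, 0.79, 0.81), cutoff = 0), 1)
  expect_warning(k <- selectDimensions(c(0.1, 0.2), cutoff = 0.8),
                 "not reached")
  expect_equal(k, 2)
  expect_warning(classicalMDS(as.matrix(dist(cbind(1:4))), kMax = 10),
                 "truncated")
})

test_that("planted array classes separate in the selected subspace", {
  skip_if_not_installed("cluster")
  groups <- rep(c("MDM", "DC", "M3DC"), each = 4)
  cfg <- simConfig(nProbes = 1200, nReplicateProbes = 20,
                   negativeControlCount = 30, nArrays = 12,
                   groupLabels = groups, groupEffect = 2,
                   groupProbeFraction = 0.08, seed = 94)
  d <- generateDataset(cfg, dir = tempfile())
  n5 <- suppressWarnings(normalizeToReference(
    buildChannelMatrix(readFeatureExtractionDir(d$dir), "Cy5"), "loess"))
  res <- classicalMDS(distanceMatrix(n5))
  k <- selectedK(res)
  sil <- cluster::silhouette(as.integer(factor(groups)),
                             dist(mdsPoints(res)[, seq_len(k)]))
  expect_gt(mean(sil[, "sil_width"]), 0)
  # at least as many informative dimensions as planted factors - 1
  expect_gte(k, 2)
})
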