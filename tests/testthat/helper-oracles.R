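# Independent brute-force oracles used to cross-check the vectorized
# implementations, plus small fixture builders.

naiveChannelStats <- function(v5, v3) {
  P <- nrow(v5)
  out <- data.frame(meanCy5 = numeric(P), meanCy3 = numeric(P),
                    sdCy5 = numeric(P), sdCy3 = numeric(P),
                    covariance = numeric(P), correlation = numeric(P))
  for (i in seq_len(P)) {
    a <- v5[i, ]; b <- v3[i, ]
    out$meanCy5[i] <- mean(a); out$meanCy3[i] <- mean(b)
    out$sdCy5[i] <- sd(a); out$sdCy3[i] <- sd(b)
    out$covariance[i] <- cov(a, b)
    out$correlation[i] <- cor(a, b)
  }
  out
}

naiveDistanceMatrix <- function(v) {
  n <- ncol(v)
  d <- matrix(0, n, n, dimnames = list(colnames(v), colnames(v)))
  for (i in seq_len(n))
    for (j in seq_len(n))
      d[i, j] <- sqrt(sum((v[, i] - v[, j])^2))
  d
}

naiveCallFraction <- function(x, background, threshold) {
  on <- 0L
  for (v in x) if (v > background + threshold) on <- on + 1L
  on / length(x)
}

randomMatrix <- function(P, n, seed, mean = 8, sd = 1) {
  set.seed(seed)
  matrix(rnorm(P * n, mean, sd), P, n,
         dimnames = list(sprintf("p%04d", seq_len(P)),
                         sprintf("a%02d", seq_len(n))))
}

# A hand-built FeatureTable: one channel's signals given on the log2
# scale, identical values in the other channel.
makeFeatureTable <- function(probes, log2g, log2r = log2g,
                             controlType = rep(0L, length(probes)),
                             arrayId = "t1") {
  new("FeatureTable", arrayId = arrayId,
      features = data.frame(featureIndex = seq_along(probes),
                            probeName = probes,
                            controlType = controlType,
                            gMedianSignal = 2^log2g,
                            rMedianSignal = 2^log2r,
                            stringsAsFactors = FALSE))
}

# Write a minimal FE file by hand (independent of the package writer).
writeHandFE <- function(path, cols, rows) {
  lines <- c("FEPARAMS\tProtocol_Name", "DATA\thand", "*",
             paste(c("FEATURES", cols), collapse = "\t"),
             vapply(rows, function(r) paste(c("DATA", r), collapse = "\t"),
                    character(1)))
  writeLines(lines, path)
  path
}
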