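#' Euclidean distance matrix between arrays
#'
#' Pairwise Euclidean distance between array columns over all probes.
#'
#' @param m a [ChannelMatrix-class] or numeric probe-by-array matrix with
#'   at least two arrays.
#' @param excludeControls drop negative-control row(s) first (only for a
#'   `ChannelMatrix`).
#' @return symmetric array-by-array distance matrix with zero diagonal.
#' @export
distanceMatrix <- function(m, excludeControls = TRUE) {
  v <- .signalOf(m)
  if (is(m, "ChannelMatrix") && excludeControls)
    v <- v[!isNegativeControl(m), , drop = FALSE]
  if (ncol(v) < 2L) stop("distance matrix needs at least 2 arrays")
  if (any(!is.finite(v))) stop("non-finite values in the matrix")
  as.matrix(stats::dist(t(v), method = "euclidean"))
}

#' Classical multidimensional scaling
#'
#' Embeds the arrays in a low-dimensional Euclidean space from their
#' pairwise distances: the squared-distance matrix is double-centred
#' (`-0.5 * J %*% D^2 %*% J` with `J = I - 1/n`), eigendecomposed, and each
#' retained axis is the corresponding eigenvector scaled by the square root
#' of its (positive) eigenvalue. For Euclidean input distances this is
#' mathematically equivalent to principal component analysis of the
#' centred data. Each axis is oriented so that its largest-magnitude
#' loading is positive, making the output deterministic.
#'
#' Dimensionality is chosen with the cumulative eigenvalue goodness of fit
#' ([goodnessOfFit()]): the smallest `k` whose `P_k` reaches `cutoff`
#' (around 0.8 is a conventional choice).
#'
#' @param d distance matrix (as from [distanceMatrix()]) or `dist` object.
#' @param kMax maximum number of dimensions to retain (default `n - 1`;
#'   larger requests are truncated with a warning).
#' @param cutoff goodness-of-fit cutoff for [selectDimensions()].
#' @param annotations optional per-array annotation data.frame (row order
#'   matching `d`) carried through for plotting.
#' @return An [MDSResult-class].
#' @examples
#' v <- matrix(rnorm(200), 50, 4,
#'             dimnames = list(NULL, paste0("a", 1:4)))
#' res <- classicalMDS(distanceMatrix(v))
#' eigenvalues(res)
#' @export
classicalMDS <- function(d, kMax = NULL, cutoff = 0.8,
                         annotations = data.frame()) {
  d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d))) || any(diag(d) != 0) || any(d < 0))
    stop("'d' must be a symmetric non-negative distance matrix with zero diagonal")
  n <- nrow(d)
  if (is.null(kMax)) kMax <- n - 1L
  if (kMax >= n) {
    warning("kMax >= number of arrays; truncated to n - 1")
    kMax <- n - 1L
  }
  J <- diag(n) - 1 / n
  B <- -0.5 * J %*% d^2 %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- e$values
  npos <- sum(ev > max(ev, 0) * 1e-12 & ev > 0)
  k <- min(kMax, npos)
  pts <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), k)
  # deterministic axis orientation
  for (j in seq_len(k)) {
    i <- which.max(abs(pts[, j]))
    if (pts[i, j] < 0) pts[, j] <- -pts[, j]
  }
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("dim", seq_len(k))
  pk <- vapply(seq_len(n - 1L), function(kk) goodnessOfFit(ev, kk),
               numeric(1))
  sel <- selectDimensions(pk, cutoff = cutoff)
  new("MDSResult", eigenvalues = ev, points = pts, pk = pk,
      selectedK = as.integer(sel), cutoff = cutoff,
      annotations = as.data.frame(annotations))
}

#' Cumulative eigenvalue goodness of fit
#'
#' The fraction of the total positive eigenvalue mass captured by the
#' first `k` dimensions: `sum(max(lambda_i, 0), i <= k) /
#' sum(max(lambda_i, 0))`. Negative eigenvalues (numerical error for
#' Euclidean input) are clamped to zero; double-centring forces at least
#' one zero eigenvalue, so the denominator effectively runs over `n - 1`
#' terms and the value reaches 1 at `k = n - 1`.
#'
#' @param eigenvalues numeric eigenvalues in descending order.
#' @param k number of leading dimensions, `1 <= k <= length(eigenvalues)`.
#' @return `P_k` in `[0, 1]`.
#' @examples
#' goodnessOfFit(c(4, 3, 2, 1), 2)  # 0.7
#' @export
goodnessOfFit <- function(eigenvalues, k) {
  if (k < 1L || k > length(eigenvalues))
    stop("k must lie in [1, number of eigenvalues]")
  lp <- pmax(eigenvalues, 0)
  total <- sum(lp)
  if (total <= 0) stop("all eigenvalues are non-positive")
  sum(lp[seq_len(k)]) / total
}

#' Choose the embedding dimensionality from a goodness-of-fit curve
#'
#' @param pk non-decreasing goodness-of-fit values for k = 1, 2, ...
#' @param cutoff smallest k with `pk >= cutoff` is returned (default 0.8);
#'   if the cutoff is never reached, the last k is returned with a warning.
#' @return integer dimensionality.
#' @export
selectDimensions <- function(pk, cutoff = 0.8) {
  hit <- which(pk >= cutoff)
  if (length(hit) == 0L) {
    warning("goodness-of-fit cutoff ", cutoff,
            " not reached; returning k = ", length(pk))
    return(length(pk))
  }
  hit[1L]
}
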