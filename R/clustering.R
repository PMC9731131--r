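#' PCA reduction retaining a target fraction of variance
#'
#' Mean-centered principal-component scores keeping the smallest number of
#' components whose cumulative explained variance reaches the threshold
#' (at least one component). Used to compress the high-dimensional Zernike
#' descriptors before clustering.
#'
#' @param x numeric feature matrix (observations x features).
#' @param varianceRetained target cumulative variance fraction in `(0, 1]`
#'   (default 0.998).
#' @return score matrix with attributes `nComponents` and
#'   `varianceExplained`.
#' @export
pcaReduce <- function(x, varianceRetained = 0.998) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("at least 2 rows are required")
  if (varianceRetained <= 0 || varianceRetained > 1)
    stop("varianceRetained must lie in (0, 1]")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  v <- p$sdev^2
  if (sum(v) == 0) {
    scores <- p$x[, 1L, drop = FALSE]
    return(structure(scores, nComponents = 1L, varianceExplained = 1))
  }
  cum <- cumsum(v) / sum(v)
  ncomp <- max(1L, which(cum >= varianceRetained - 1e-12)[1L])
  structure(p$x[, seq_len(ncomp), drop = FALSE],
            nComponents = ncomp, varianceExplained = cum[ncomp])
}

#' Multi-restart K-means (Lloyd), best of `trials`
#'
#' Runs Lloyd's algorithm `trials` times with initial centroids drawn
#' uniformly without replacement from the data rows and returns the model
#' with the smallest within-cluster dispersion
#' `W_k = sum_r sum_{x in C_r} ||x - xbar_r||^2`. Fully deterministic given
#' `seed`; trials whose initial draw collapses (duplicate centers or an
#' empty cluster) are re-drawn within the trial.
#'
#' @param x numeric feature matrix.
#' @param k number of clusters (`k <= nrow(x)`).
#' @param trials number of random restarts (default 1000).
#' @param seed integer seed.
#' @return A [ClusterModel-class] object.
#' @export
kmeansBestOf <- function(x, k, trials = 1000L, seed = 1L) {
  x <- as.matrix(x)
  k <- as.integer(k)
  if (k > nrow(x)) stop("k cannot exceed the number of rows")
  if (trials < 1L) stop("trials must be >= 1")
  if (k == 1L) {
    ctr <- matrix(colMeans(x), 1L)
    Wk <- sum(sweep(x, 2, ctr)^2)
    return(new("ClusterModel", k = 1L,
               assignments = rep(1L, nrow(x)), centroids = ctr, Wk = Wk))
  }
  best <- NULL
  withSeed(seed, {
    for (t in seq_len(trials)) {
      fit <- NULL
      for (attempt in 1:100) {
        centers <- x[sample.int(nrow(x), k), , drop = FALSE]
        fit <- tryCatch(
          suppressWarnings(stats::kmeans(x, centers = centers,
                                         iter.max = 100L,
                                         algorithm = "Lloyd")),
          error = function(e) NULL)
        if (!is.null(fit)) break
      }
      if (is.null(fit)) stop("k-means failed: too few distinct rows for k = ", k)
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  new("ClusterModel", k = k, assignments = as.integer(best$cluster),
      centroids = unname(best$centers), Wk = best$tot.withinss)
}

# Eq.-style selection rule: smallest k with gap(k) >= gap(k+1) - s(k+1)
selectK <- function(gap, sk) {
  N <- length(gap)
  for (k in seq_len(N - 1L)) {
    if (gap[k] >= gap[k + 1L] - sk[k + 1L]) return(as.integer(k))
  }
  as.integer(N)
}

#' Gap statistic for cluster-count selection
#'
#' For `k = 1..N` computes the within-cluster dispersion of the data and of
#' `B` reference datasets sampled uniformly from the per-dimension bounding
#' box of the data, then `Gap(k) = mean_b log(W*_kb) - log(W_k)`, the
#' reference dispersion spread `sd_k` and `s_k = sd_k * sqrt(1 + 1/B)`. The
#' selected count is the smallest `k` with
#' `Gap(k) >= Gap(k + 1) - s_{k+1}` (falling back to `N` when no k
#' qualifies). All randomness is derived from `seed` through documented
#' sub-streams.
#'
#' @param x numeric feature matrix.
#' @param N maximum cluster count to examine (default 20, capped at
#'   `nrow(x) - 1`).
#' @param B number of uniform reference datasets (default 30).
#' @param seed master seed.
#' @param trialsPerFit K-means restarts for the data fits.
#' @param refTrials restarts for the reference fits (defaults to
#'   `trialsPerFit`; a smaller budget is a common speed/quality trade).
#' @return A [GapCurve-class] object.
#' @export
gapStatistic <- function(x, N = 20L, B = 30L, seed = 1L,
                         trialsPerFit = 100L, refTrials = trialsPerFit) {
  x <- as.matrix(x)
  if (N < 2L) stop("N must be >= 2")
  if (B < 2L) stop("B must be >= 2")
  nDistinct <- nrow(unique(x))
  N <- as.integer(min(N, nrow(x) - 1L, nDistinct))
  if (N < 2L) stop("too few rows for a gap curve")
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  if (max(hi - lo) == 0) stop("degenerate bounding box: all features constant")
  Wk <- vapply(seq_len(N), function(k)
    kmeansBestOf(x, k, trialsPerFit, subSeed(seed, k))@Wk, numeric(1))
  logWstar <- matrix(0, B, N)
  for (b in seq_len(B)) {
    ref <- withSeed(subSeed(seed, 10000L + b), {
      matrix(stats::runif(length(x), rep(lo, each = nrow(x)),
                          rep(hi, each = nrow(x))), nrow(x))
    })
    logWstar[b, ] <- vapply(seq_len(N), function(k)
      log(kmeansBestOf(ref, k, refTrials,
                       subSeed(seed, 20000L + b * 100L + k))@Wk), numeric(1))
  }
  lbar <- colMeans(logWstar)
  gap <- lbar - log(Wk)
  sdk <- sqrt(colMeans(sweep(logWstar, 2, lbar)^2))
  sk <- sdk * sqrt(1 + 1 / B)
  new("GapCurve", k = seq_len(N), Wk = Wk, logWkbMean = lbar, gap = gap,
      sdk = sdk, sk = sk, kHat = selectK(gap, sk),
      B = as.integer(B), N = N)
}

#' Cluster representatives closest to the centroids
#'
#' For each cluster returns the row identifiers with the smallest Euclidean
#' distance to the cluster centroid, in ascending distance order (ties broken
#' by row id). Clusters smaller than `perCluster` return all their members.
#'
#' @param model a [ClusterModel-class].
#' @param x the feature matrix the model was fitted on.
#' @param perCluster number of representatives per cluster (default 4).
#' @return named list (one element per cluster) of row ids.
#' @export
representatives <- function(model, x, perCluster = 4L) {
  if (perCluster < 1L) stop("perCluster must be >= 1")
  x <- as.matrix(x)
  ids <- rownames(x); if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  out <- vector("list", model@k)
  names(out) <- paste0("cluster_", seq_len(model@k))
  for (cl in seq_len(model@k)) {
    member <- which(model@assignments == cl)
    d <- sqrt(rowSums(sweep(x[member, , drop = FALSE], 2,
                            model@centroids[cl, ])^2))
    ord <- order(d, member)
    out[[cl]] <- ids[member[ord]][seq_len(min(perCluster, length(member)))]
  }
  out
}

#' @describeIn gapStatistic compact display
#' @param object a `GapCurve`
#' @export
setMethod("show", "GapCurve", function(object) {
  cat("GapCurve: k = 1..", object@N, " (B = ", object@B, "), selected k = ",
      object@kHat, "\n", sep = "")
})

#' @describeIn kmeansBestOf compact display
#' @param object a `ClusterModel`
#' @export
setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel: k = %d, n = %d, Wk = %.4g\n",
              object@k, length(object@assignments), object@Wk))
})
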