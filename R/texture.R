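#' Min-max intensity normalization with low-tail discard
#'
#' Drops voxels below the per-lesion lower quantile (linear-interpolation
#' estimator; 1% by default — segmentation false positives concentrate in
#' the dim boundary voxels), then maps the retained intensities to `[0, 1]`
#' by `s = (clamp(f, gMin, gMax) - gMin) / (gMax - gMin)` where `gMin` and
#' `gMax` are the minimum and maximum of the retained set.
#'
#' @param lesion a [Lesion3D-class] or a numeric vector of intensities.
#' @param discardFraction fraction of the low tail to discard (default 0.01).
#' @return numeric vector of normalized intensities in `[0, 1]`.
#' @export
normalizeIntensities <- function(lesion, discardFraction = 0.01) {
  f <- if (is(lesion, "Lesion3D")) lesion@intensities else as.numeric(lesion)
  if (!length(f)) stop("no intensities")
  # median-unbiased linear-interpolation quantile: for very small lesions the
  # 1% point falls at the minimum (nothing discarded), while genuine low
  # outliers in larger voxel sets fall below it
  q <- stats::quantile(f, discardFraction, names = FALSE, type = 8)
  keep <- f[f >= q]
  gMin <- min(keep); gMax <- max(keep)
  if (gMax == gMin)
    stop("degenerate lesion: constant intensity after discarding")
  (clamp(keep, gMin, gMax) - gMin) / (gMax - gMin)
}

#' Fuzzy intensity histogram
#'
#' Allocates each normalized intensity `s` fuzzily to the two bins whose
#' centers `(2j + 1) / (2n)` bracket it, splitting its unit mass linearly by
#' distance; values below the first center give all mass to bin 0, values
#' above the last center to bin `n - 1`. The histogram is finally divided by
#' the number of contributing voxels so the frequencies sum to exactly 1,
#' making the feature independent of lesion size, voxel order, and any rigid
#' rotation.
#'
#' @param s normalized intensities in `[0, 1]` (see [normalizeIntensities()]).
#' @param nBins number of bins (default 10).
#' @param lesionId provenance identifier stored with the histogram.
#' @return A [FuzzyHistogram-class] object.
#' @examples
#' fuzzyHistogram(c(0.04, 0.12, 0.5), nBins = 10)
#' @export
fuzzyHistogram <- function(s, nBins = 10L, lesionId = "lesion") {
  if (!length(s)) stop("empty input")
  if (any(s < 0 | s > 1)) stop("s must lie in [0, 1]")
  n <- as.integer(nBins)
  if (n < 2L) stop("nBins must be >= 2")
  t <- s * n - 0.5          # position on the bin-center axis
  h <- numeric(n)
  low <- t <= 0; high <- t >= n - 1
  h[1L] <- sum(low)
  h[n] <- h[n] + sum(high)
  mid <- !(low | high)
  if (any(mid)) {
    j <- floor(t[mid]); fr <- t[mid] - j
    agg <- rowsum(c(1 - fr, fr), c(j, j + 1))
    b <- as.integer(rownames(agg)) + 1L
    h[b] <- h[b] + agg[, 1]
  }
  new("FuzzyHistogram", nBins = n, frequencies = h / length(s),
      lesionId = as.character(lesionId))
}

#' Texture feature table for a set of lesions
#'
#' Convenience wrapper producing one fuzzy histogram row per lesion.
#' Degenerate (constant-intensity) lesions are dropped with a warning.
#'
#' @param lesions list of [Lesion3D-class].
#' @param nBins number of bins.
#' @param discardFraction low-tail discard fraction.
#' @return numeric matrix (lesions x bins) with rownames
#'   `subjectId.lesionId`; attribute `dropped` lists skipped lesions.
#' @export
textureFeatures <- function(lesions, nBins = 10L, discardFraction = 0.01) {
  rows <- list(); dropped <- character()
  for (x in lesions) {
    id <- paste0(x@subjectId, ".", x@lesionId)
    s <- tryCatch(normalizeIntensities(x, discardFraction),
                  error = function(e) NULL)
    if (is.null(s)) { dropped <- c(dropped, id); next }
    rows[[id]] <- fuzzyHistogram(s, nBins, id)@frequencies
  }
  if (length(dropped))
    warning("dropped degenerate lesions: ", paste(dropped, collapse = ", "))
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- matrix(numeric(0), 0, nBins)
  colnames(out) <- paste0("bin_", seq_len(nBins) - 1L)
  structure(out, dropped = dropped)
}

#' @describeIn fuzzyHistogram compact display
#' @param object a `FuzzyHistogram`
#' @export
setMethod("show", "FuzzyHistogram", function(object) {
  cat("FuzzyHistogram (", object@lesionId, "), ", object@nBins, " bins: ",
      paste(sprintf("%.3f", object@frequencies), collapse = " "), "\n", sep = "")
})
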