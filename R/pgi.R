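#' Pooled lesion-intensity statistics of a subject
#'
#' Mean and population standard deviation of the voxel intensities pooled
#' over all of the subject's lesions; these define the penumbra growth
#' threshold `m - gamma * sigma`.
#'
#' @param lesions list of [Lesion3D-class] from one subject (or a numeric
#'   vector of pooled intensities).
#' @return list with `m`, `sigma` and `nVoxels`.
#' @export
subjectIntensityStats <- function(lesions) {
  f <- if (is.numeric(lesions)) lesions
       else unlist(lapply(lesions, function(x) x@intensities))
  if (!length(f)) stop("no lesion voxels")
  m <- mean(f)
  list(m = m, sigma = sqrt(mean((f - m)^2)), nVoxels = length(f))
}

#' Build one-voxel-thick penumbra layers around a lesion
#'
#' Layer `i` consists of the voxels added by the i-th morphological dilation
#' of the lesion mask (`dilation^i minus dilation^(i-1)`), excluding voxels
#' that belong to any lesion of the subject and voxels outside the image.
#' The default structuring element is the full 3x3x3 neighbourhood
#' (26-connectivity), so layers are one voxel thick in every direction.
#'
#' @param lesionMask binary 3D array of the lesion of interest.
#' @param allLesionsMask binary 3D array of all lesions of the subject
#'   (must contain `lesionMask`); defaults to `lesionMask`.
#' @param nLayers number of shells `l` (default 5).
#' @param connectivity structuring element: 6, 18 or 26 (default).
#' @return A [PenumbraLayers-class] with growth counts unset.
#' @export
buildPenumbraLayers <- function(lesionMask, allLesionsMask = lesionMask,
                                nLayers = 5L, connectivity = 26L) {
  if (!identical(dim(lesionMask), dim(allLesionsMask)))
    stop("masks must have the same shape")
  if (nLayers < 1L) stop("nLayers must be >= 1")
  lesion <- lesionMask > 0
  if (!any(lesion)) stop("empty lesion mask")
  excl <- allLesionsMask > 0
  if (any(lesion & !excl)) stop("lesionMask must be contained in allLesionsMask")
  l <- as.integer(nLayers)
  layers <- vector("list", l)
  cur <- lesion
  for (i in seq_len(l)) {
    dil <- dilateMask(cur, connectivity)
    layers[[i]] <- which(dil & !cur & !excl)
    cur <- dil
  }
  new("PenumbraLayers",
      nLayers = l, layerVoxels = layers,
      layerSizes = vapply(layers, length, integer(1)),
      growthCounts = rep(NA_integer_, l),
      weights = seq_len(l) / sum(seq_len(l)),
      gamma = NA_real_, dim = dim(lesionMask))
}

#' Count supra-threshold (growth) voxels per penumbra layer
#'
#' A penumbra voxel counts as a potential growth voxel when its intensity
#' satisfies `m - f <= gamma * sigma`, i.e. `f >= m - gamma * sigma`. At the
#' default `gamma = 2.5` the threshold covers 99.38% of lesion intensities
#' under a Gaussian model (see [penumbraCoverage()]).
#'
#' @param layers a [PenumbraLayers-class].
#' @param volume the intensity volume the layers were built on.
#' @param stats output of [subjectIntensityStats()].
#' @param gamma positive threshold multiplier (default 2.5).
#' @return the layers object with `growthCounts` and `gamma` filled in.
#' @export
countGrowthVoxels <- function(layers, volume, stats, gamma = 2.5) {
  if (!identical(as.integer(dim(volume)), as.integer(layers@dim)))
    stop("volume shape does not match the layers")
  thr <- stats$m - gamma * stats$sigma
  layers@growthCounts <- vapply(layers@layerVoxels, function(ix)
    sum(volume[ix] >= thr), integer(1))
  layers@gamma <- gamma
  validObject(layers)
  layers
}

#' Potential Growth Index
#'
#' `PGI = sum_i GV_i * w_i / V_l` where `GV_i` is the growth-voxel count of
#' layer `i`, `w_i = i / sum(1..l)` weights outer layers more heavily, and
#' `V_l` is the total penumbra size. PGI lies in `[0, 1]` and is 0 exactly
#' when no penumbra voxel is supra-threshold.
#'
#' @param layers a [PenumbraLayers-class] with growth counts filled in
#'   (see [countGrowthVoxels()]).
#' @param lesionId identifier stored in the result.
#' @return A [PGIResult-class] object.
#' @export
computePGI <- function(layers, lesionId = "lesion") {
  if (any(is.na(layers@growthCounts)))
    stop("growth counts not set; run countGrowthVoxels() first")
  Vl <- sum(layers@layerSizes)
  if (Vl == 0L) stop("zero-size penumbra: the lesion fills the image")
  new("PGIResult",
      lesionId = as.character(lesionId),
      pgi = sum(layers@growthCounts * layers@weights) / Vl,
      gamma = layers@gamma, nLayers = layers@nLayers,
      layerSizes = layers@layerSizes, growthCounts = layers@growthCounts,
      weights = layers@weights)
}

#' One-sided Gaussian coverage of the growth threshold
#'
#' Fraction of lesion voxel intensities above `m - gamma * sigma` under a
#' Gaussian intensity model: `Phi(gamma)`. At `gamma = 2.5` this is 0.99379,
#' i.e. 99.38% coverage.
#'
#' @param gamma threshold multiplier.
#' @return coverage probability.
#' @export
penumbraCoverage <- function(gamma) stats::pnorm(gamma)

#' PGI for every lesion of a subject
#'
#' Convenience wrapper: pools the subject statistics, builds the penumbra
#' layers of each lesion against the union mask of all lesions, counts
#' growth voxels and assembles the per-lesion PGI table.
#'
#' @param volume subject intensity volume.
#' @param lesions list of the subject's [Lesion3D-class] objects.
#' @param nLayers,gamma,connectivity see [buildPenumbraLayers()] and
#'   [countGrowthVoxels()].
#' @return data.frame with one row per lesion: subject_id, lesion_id, PGI,
#'   gamma, l, `V_1..V_l`, `GV_1..GV_l`.
#' @export
subjectPGI <- function(volume, lesions, nLayers = 5L, gamma = 2.5,
                       connectivity = 26L) {
  if (!length(lesions)) return(data.frame())
  dims <- dim(volume)
  allMask <- array(FALSE, dims)
  for (x in lesions) allMask[coordsToLinear(x@coords, dims)] <- TRUE
  stats <- subjectIntensityStats(lesions)
  rows <- lapply(lesions, function(x) {
    mask <- array(FALSE, dims)
    mask[coordsToLinear(x@coords, dims)] <- TRUE
    layers <- buildPenumbraLayers(mask, allMask, nLayers, connectivity)
    layers <- countGrowthVoxels(layers, volume, stats, gamma)
    res <- computePGI(layers, paste0(x@subjectId, ".", x@lesionId))
    cbind(data.frame(subject_id = x@subjectId, lesion_id = x@lesionId,
                     PGI = res@pgi, gamma = gamma, l = nLayers),
          as.data.frame(as.list(stats::setNames(
            c(res@layerSizes, res@growthCounts),
            c(paste0("V_", seq_len(nLayers)),
              paste0("GV_", seq_len(nLayers)))))))
  })
  do.call(rbind, rows)
}

#' @describeIn computePGI compact display
#' @param object a `PGIResult`
#' @export
setMethod("show", "PGIResult", function(object) {
  cat(sprintf("PGIResult %s: PGI = %.4f (gamma = %.2f, l = %d)\n",
              object@lesionId, object@pgi, object@gamma, object@nLayers))
})

#' @describeIn buildPenumbraLayers compact display
#' @param object a `PenumbraLayers`
#' @export
setMethod("show", "PenumbraLayers", function(object) {
  cat("PenumbraLayers:", object@nLayers, "shells, sizes",
      paste(object@layerSizes, collapse = "/"),
      if (all(is.na(object@growthCounts))) "(growth counts unset)"
      else paste0("growth ", paste(object@growthCounts, collapse = "/")), "\n")
})
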