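#' Extract connected WMH lesions from a volume and mask
#'
#' Labels the connected components of a binary lesion mask (26-connectivity
#' by default) and keeps those with physical volume strictly greater than
#' `minVolumeMm3`. Each retained component carries its voxel coordinates,
#' intensities from the co-registered volume, unweighted centroid and
#' volumes.
#'
#' @param volume 3D numeric intensity array (e.g. read with [readVolume()]).
#' @param mask binary 3D array of the same shape (values 0/1).
#' @param minVolumeMm3 minimum physical volume; components at or below it are
#'   dropped (strict greater-than rule). Default 30.
#' @param spacing voxel spacing in mm per axis; taken from the volume's NIfTI
#'   header when available.
#' @param connectivity 6, 18 or 26 (default).
#' @param subjectId identifier stored in each lesion.
#' @return list of [Lesion3D-class] objects, ordered by first voxel index.
#' @export
extractLesions <- function(volume, mask, minVolumeMm3 = 30,
                           spacing = NULL, connectivity = 26L,
                           subjectId = "subject") {
  if (!identical(dim(volume), dim(mask)))
    stop("volume and mask must have the same shape")
  vals <- unique(as.vector(mask))
  if (!all(vals %in% c(0, 1))) stop("mask must be binary (0/1)")
  if (is.null(spacing)) {
    spacing <- tryCatch(RNifti::pixdim(volume)[1:3], error = function(e) NULL)
    if (is.null(spacing) || !length(spacing) || any(!is.finite(spacing)) ||
        any(spacing <= 0)) spacing <- c(1, 1, 1)
  }
  voxVol <- prod(spacing)
  comps <- labelComponents(mask, connectivity)
  dims <- dim(mask)
  out <- list()
  for (i in seq_along(comps)) {
    idx <- comps[[i]]
    if (length(idx) * voxVol <= minVolumeMm3) next
    coords <- arrayInd(idx, dims)
    out[[length(out) + 1L]] <- new("Lesion3D",
      subjectId = subjectId, lesionId = length(out) + 1L,
      coords = coords, intensities = as.numeric(volume[idx]),
      centroid = colMeans(coords),
      volumeVoxels = length(idx), volumeMm3 = length(idx) * voxVol,
      spacing = as.numeric(spacing))
  }
  out
}

#' Split lesions into small and large size groups
#'
#' Partition at `cutoffVoxels`; lesions at the boundary go to the small
#' group.
#'
#' @param lesions list of [Lesion3D-class].
#' @param cutoffVoxels inclusive upper bound of the small group. Default 250.
#' @return list with elements `small`, `large` (lesion lists) and `cutoff`.
#' @export
splitBySize <- function(lesions, cutoffVoxels = 250L) {
  sizes <- vapply(lesions, function(x) x@volumeVoxels, integer(1))
  list(small = lesions[sizes <= cutoffVoxels],
       large = lesions[sizes > cutoffVoxels],
       cutoff = as.integer(cutoffVoxels))
}

#' Rescale a lesion shape to a target volume
#'
#' Rescales the binary occupancy isotropically by `(v' / v)^(1/3)`,
#' interpolates (tricubic by default), and thresholds at the intensity
#' level whose resulting foreground count is closest to the target; ties
#' pick the lower threshold, i.e. the larger volume. A single-voxel lesion
#' upscaled falls back to nearest-neighbour block replication.
#'
#' @param lesion a [Lesion3D-class] or a binary 3D array.
#' @param targetVoxels desired foreground count `v' >= 1`.
#' @param interpolation `"tricubic"` (default) or `"trilinear"`.
#' @return binary 3D array tightly containing the rescaled shape.
#' @export
rescaleToTargetVolume <- function(lesion, targetVoxels,
                                  interpolation = c("tricubic", "trilinear")) {
  interpolation <- match.arg(interpolation)
  if (targetVoxels < 1) stop("targetVoxels must be >= 1")
  shape <- if (is(lesion, "Lesion3D")) lesionToArray(lesion) else (lesion > 0) * 1
  v <- sum(shape)
  if (v == 0) stop("empty lesion")
  a <- (targetVoxels / v)^(1 / 3)
  if (v == 1 && targetVoxels > 1) {
    s <- max(1L, as.integer(round(a)))
    return(array(1, c(s, s, s)))
  }
  # pad so the smoothing support of the kernel stays inside the array
  pad <- 2L
  dims <- dim(shape)
  padded <- array(0, dims + 2L * pad)
  padded[pad + seq_len(dims[1]), pad + seq_len(dims[2]), pad + seq_len(dims[3])] <- shape
  inCtr <- (dim(padded) + 1) / 2
  outDim <- pmax(3L, as.integer(ceiling(dims * a))) + 2L
  outCtr <- (outDim + 1) / 2
  g <- as.matrix(expand.grid(x = seq_len(outDim[1]), y = seq_len(outDim[2]),
                             z = seq_len(outDim[3])))
  pts <- sweep(sweep(g, 2, outCtr), 2, rep(1 / a, 3), "*")
  pts <- sweep(pts, 2, inCtr, "+")
  vals <- interp3d(padded, pts, interpolation)
  thr <- bestVolumeThreshold(vals, targetVoxels)
  array(as.numeric(vals >= thr), outDim)
}

# threshold over the observed interpolated values whose foreground count is
# closest to the target; ties resolved toward the larger volume
bestVolumeThreshold <- function(vals, target) {
  cand <- sort(unique(vals[vals > 0]), decreasing = TRUE)
  counts <- vapply(cand, function(t) sum(vals >= t), numeric(1))
  d <- abs(counts - target)
  best <- which(d == min(d))
  cand[best[length(best)]]   # lowest threshold among the tied candidates
}

lesionToArray <- function(lesion) {
  lo <- apply(lesion@coords, 2, min); hi <- apply(lesion@coords, 2, max)
  arr <- array(0, hi - lo + 1L)
  arr[cbind(lesion@coords[, 1] - lo[1] + 1L,
            lesion@coords[, 2] - lo[2] + 1L,
            lesion@coords[, 3] - lo[3] + 1L)] <- 1
  arr
}

#' Center a shape in a cube
#'
#' Places the shape's centroid at the cube's geometric center (0-based index
#' `floor((N - 1) / 2)` per axis, shift rounded to the nearest voxel). The
#' voxel count is preserved exactly; an error is raised when the shape does
#' not fit.
#'
#' @param shape binary 3D array.
#' @param cubeSide target cube side `N`.
#' @return binary `N^3` array.
#' @export
embedInCube <- function(shape, cubeSide) {
  N <- as.integer(cubeSide)
  coords <- which(shape > 0, arr.ind = TRUE)
  if (!nrow(coords)) stop("empty shape")
  centroid <- colMeans(coords)
  target <- floor((N - 1) / 2) + 1   # 1-based center index
  shift <- round(target - centroid)
  newc <- sweep(coords, 2, shift, "+")
  if (any(newc < 1) || any(newc > N))
    stop("lesion extent exceeds the cube")
  out <- array(0, c(N, N, N))
  out[newc] <- 1
  out
}

#' Summary table for a list of lesions
#'
#' @param lesions list of [Lesion3D-class].
#' @param cutoffVoxels size-group cutoff used for the `group` column.
#' @return data.frame with one row per lesion.
#' @export
lesionTable <- function(lesions, cutoffVoxels = 250L) {
  if (!length(lesions))
    return(data.frame(subject_id = character(), lesion_id = integer(),
                      volume_voxels = integer(), volume_mm3 = numeric(),
                      centroid_x = numeric(), centroid_y = numeric(),
                      centroid_z = numeric(), group = character()))
  do.call(rbind, lapply(lesions, function(x)
    data.frame(subject_id = x@subjectId, lesion_id = x@lesionId,
               volume_voxels = x@volumeVoxels, volume_mm3 = x@volumeMm3,
               centroid_x = x@centroid[1], centroid_y = x@centroid[2],
               centroid_z = x@centroid[3],
               group = if (x@volumeVoxels <= cutoffVoxels) "small" else "large")))
}

#' @describeIn extractLesions compact display of a lesion
#' @param object a `Lesion3D`
#' @export
setMethod("show", "Lesion3D", function(object) {
  cat(sprintf("Lesion3D %s/%d: %d voxels (%.1f mm^3), centroid (%.1f, %.1f, %.1f)\n",
              object@subjectId, object@lesionId, object@volumeVoxels,
              object@volumeMm3, object@centroid[1], object@centroid[2],
              object@centroid[3]))
})
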