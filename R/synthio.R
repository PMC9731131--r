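# Synthetic FLAIR-like phantoms with exact ground truth, plus NIfTI I/O.
#
# The generator is the test-data contract for every other module: its
# ground-truth record predicts the outputs of extractLesions(),
# buildPenumbraLayers() and countGrowthVoxels() exactly on noise-free
# phantoms, because layer membership is derived here from Chebyshev
# distances (an independent route from the dilation code) and penumbra
# intensities are placed on the correct side of the growth threshold by
# construction.

#' Specify a synthetic phantom
#'
#' @param dim image dimensions (default `c(64, 64, 64)`).
#' @param lesions list of lesion primitives; each is a list with `type`
#'   (`"ellipsoid"`, `"torus"` or `"blob"`), `center` (1-based voxel
#'   coordinates) and type-specific geometry: ellipsoid `radii` (3 semi-axes,
#'   voxels) and optional `rotation` (3x3 matrix); torus `R` (ring radius)
#'   and `r` (tube radius); blob `spheres` (matrix with columns x, y, z,
#'   radius). Optional per-lesion `growthFractions` gives the designed
#'   fraction of supra-threshold voxels per penumbra layer (recycled to
#'   `penumbraLayers`; default 0.5).
#' @param background background intensity (default 100).
#' @param coreIntensity intensity added to the background inside a lesion
#'   plateau (default 80).
#' @param falloffWidth width (voxels) of the smooth cosine intensity falloff
#'   from the plateau toward the lesion boundary (default 2; 0 disables it,
#'   giving a flat lesion).
#' @param penumbraLayers number of ground-truth penumbra layers (default 5).
#' @param gamma growth-threshold multiplier the halo is designed against
#'   (default 2.5).
#' @param noiseSd additive Gaussian noise SD (default 0; the ground truth is
#'   exact only without noise).
#' @param allowOverlap allow lesions (or their penumbras) to overlap
#'   (default FALSE: overlap is an error).
#' @param seed master seed; the spec plus seed fully determine the output.
#' @return a validated phantom specification (list).
#' @seealso [makePhantom()]
#' @export
phantomSpec <- function(dim = c(64, 64, 64), lesions = list(),
                        background = 100, coreIntensity = 80,
                        falloffWidth = 2, penumbraLayers = 5L, gamma = 2.5,
                        noiseSd = 0, allowOverlap = FALSE, seed = 1L) {
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < 4L)) stop("dim must be three values >= 4")
  for (les in lesions) {
    if (!is.list(les) || is.null(les$type) || is.null(les$center))
      stop("each lesion needs a type and a center")
    if (!les$type %in% c("ellipsoid", "torus", "blob"))
      stop("unknown lesion type: ", les$type)
  }
  list(dim = dim, lesions = lesions, background = background,
       coreIntensity = coreIntensity, falloffWidth = falloffWidth,
       penumbraLayers = as.integer(penumbraLayers), gamma = gamma,
       noiseSd = noiseSd, allowOverlap = isTRUE(allowOverlap),
       seed = as.integer(seed))
}

# rasterize one primitive to a logical array
rasterizeLesion <- function(les, dims) {
  ax <- lapply(1:3, function(i) seq_len(dims[i]) - les$center[i])
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  inside <- switch(les$type,
    ellipsoid = {
      p <- as.matrix(g)
      if (!is.null(les$rotation)) p <- p %*% les$rotation
      (p[, 1] / les$radii[1])^2 + (p[, 2] / les$radii[2])^2 +
        (p[, 3] / les$radii[3])^2 <= 1
    },
    torus = {
      (sqrt(g$x^2 + g$y^2) - les$R)^2 + g$z^2 <= les$r^2
    },
    blob = {
      sp <- as.matrix(les$spheres)
      hit <- rep(FALSE, nrow(g))
      for (i in seq_len(nrow(sp)))
        hit <- hit | ((g$x + les$center[1] - sp[i, 1])^2 +
                      (g$y + les$center[2] - sp[i, 2])^2 +
                      (g$z + les$center[3] - sp[i, 3])^2 <= sp[i, 4]^2)
      hit
    })
  array(inside, dims)
}

# Chebyshev-distance layer membership: independent of dilateMask()
chebyshevLayers <- function(mask, nLayers, excl) {
  dims <- dim(mask)
  coords <- which(mask, arr.ind = TRUE)
  lo <- pmax(apply(coords, 2, min) - nLayers, 1L)
  hi <- pmin(apply(coords, 2, max) + nLayers, dims)
  cand <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3]))
  candLin <- coordsToLinear(cand, dims)
  keep <- !excl[candLin]
  cand <- cand[keep, , drop = FALSE]; candLin <- candLin[keep]
  d <- rep(Inf, nrow(cand))
  for (i in seq_len(nrow(coords))) {   # lesions in phantoms are small
    di <- pmax(abs(cand[, 1] - coords[i, 1]),
               pmax(abs(cand[, 2] - coords[i, 2]),
                    abs(cand[, 3] - coords[i, 3])))
    d <- pmin(d, di)
  }
  lapply(seq_len(nLayers), function(i) sort(candLin[d == i]))
}

#' Generate a synthetic FLAIR-like volume with exact ground truth
#'
#' Builds the lesion masks from the primitives, fills the lesions with a
#' plateau intensity and a smooth cosine falloff toward the boundary, and
#' designs the penumbra: in layer `i` the first
#' `round(growthFractions[i] * V_i)` voxels (in voxel order) are set exactly
#' at the pooled lesion mean `m` (supra-threshold by construction) and the
#' rest far below `m - gamma * sigma`. Background noise, if requested, is
#' added last. Identical specs and seeds yield bit-identical output.
#'
#' @param spec a [phantomSpec()].
#' @return list with `volume` (numeric array), `mask` (0/1 array) and
#'   `truth`: per-lesion `volumeVoxels`, `centroid`, `layerSizes`,
#'   `growthCounts`, plus pooled `m`, `sigma`, the growth threshold and the
#'   designed `pgi` of each lesion.
#' @export
makePhantom <- function(spec) {
  dims <- spec$dim
  masks <- lapply(spec$lesions, rasterizeLesion, dims = dims)
  mask <- array(FALSE, dims)
  for (mk in masks) {
    if (!spec$allowOverlap && any(mask & mk))
      stop("overlapping lesion primitives (allowOverlap = FALSE)")
    mask <- mask | mk
  }
  vol <- array(spec$background, dims)
  # plateau + cosine falloff, via erosion depth
  for (mk in masks) {
    if (!any(mk)) stop("a lesion primitive rasterized to zero voxels")
    depth <- array(0L, dims)
    cur <- mk
    w <- max(0L, as.integer(ceiling(spec$falloffWidth)))
    for (dstep in seq_len(w + 1L)) {
      depth[cur] <- dstep
      cur <- cur & !dilateMask(!cur, 6L)   # city-block erosion: thin
                                           # structures keep an interior ramp
      if (!any(cur)) break
    }
    ramp <- clamp((depth[mk] - 0.5) / max(spec$falloffWidth, 0.5), 0, 1)
    vol[mk] <- spec$background + spec$coreIntensity *
      (0.5 - 0.5 * cos(pi * ramp))
  }
  fLesion <- vol[mask]
  m <- mean(fLesion)
  sigma <- sqrt(mean((fLesion - m)^2))
  thr <- m - spec$gamma * sigma
  lowVal <- thr - 6 * max(sigma, 1) - 1
  truthLesions <- list()
  claimed <- array(FALSE, dims)
  for (j in seq_along(masks)) {
    mk <- masks[[j]]
    layers <- chebyshevLayers(mk, spec$penumbraLayers, excl = mask)
    halo <- unlist(layers)
    if (!spec$allowOverlap && any(claimed[halo]))
      stop("overlapping lesion penumbras (allowOverlap = FALSE)")
    claimed[halo] <- TRUE
    gf <- spec$lesions[[j]]$growthFractions
    if (is.null(gf)) gf <- 0.5
    gf <- rep_len(gf, spec$penumbraLayers)
    gv <- integer(spec$penumbraLayers)
    for (i in seq_len(spec$penumbraLayers)) {
      Vi <- length(layers[[i]])
      gv[i] <- as.integer(round(gf[i] * Vi))
      grow <- layers[[i]][seq_len(gv[i])]
      rest <- setdiff(layers[[i]], grow)
      vol[grow] <- m
      vol[rest] <- lowVal
    }
    coords <- which(mk, arr.ind = TRUE)
    w <- seq_len(spec$penumbraLayers) / sum(seq_len(spec$penumbraLayers))
    truthLesions[[j]] <- list(
      volumeVoxels = nrow(coords), centroid = colMeans(coords),
      layerSizes = vapply(layers, length, integer(1)), growthCounts = gv,
      pgi = sum(gv * w) / max(1L, length(halo)))
  }
  if (spec$noiseSd > 0) {
    vol <- vol + withSeed(spec$seed,
      array(stats::rnorm(prod(dims), 0, spec$noiseSd), dims))
  }
  list(volume = vol, mask = array(as.numeric(mask), dims),
       truth = list(lesions = truthLesions, m = m, sigma = sigma,
                    threshold = thr, gamma = spec$gamma, seed = spec$seed))
}

#' Gaussian blob features for clustering tests
#'
#' `k` Gaussian clusters with unit within-cluster SD, centers placed
#' `separation` apart along alternating axes; fully seeded.
#'
#' @param k number of clusters.
#' @param nPerCluster points per cluster.
#' @param separation center separation in SD units.
#' @param dim feature dimension.
#' @param seed integer seed.
#' @return numeric matrix with attribute `labels` giving the true cluster
#'   of each row.
#' @export
makeBlobFeatures <- function(k, nPerCluster = 50L, separation = 10,
                             dim = 2L, seed = 1L) {
  if (k < 1L) stop("k must be >= 1")
  centers <- matrix(0, k, dim)
  if (k > 1L) for (j in 2:k)
    centers[j, ((j - 2L) %% dim) + 1L] <- separation * (1L + (j - 2L) %/% dim)
  x <- withSeed(seed, {
    pts <- matrix(stats::rnorm(k * nPerCluster * dim), k * nPerCluster, dim)
    pts + centers[rep(seq_len(k), each = nPerCluster), , drop = FALSE]
  })
  structure(x, labels = rep(seq_len(k), each = nPerCluster))
}

#' Read / write NIfTI volumes
#'
#' Thin wrappers over RNifti preserving voxel data and spacing.
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @return `readVolume` returns the image as an array-like `niftiImage`;
#'   `writeVolume` returns `path` invisibly.
#' @export
readVolume <- function(path) RNifti::readNifti(path)

#' @rdname readVolume
#' @param x numeric array to write.
#' @param spacing voxel spacing in mm per axis (default 1 mm isotropic).
#' @export
writeVolume <- function(x, path, spacing = c(1, 1, 1)) {
  img <- RNifti::asNifti(unclass(x))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname readVolume
#' @description `niftiRoundtrip` writes and re-reads a volume; the returned
#'   image has identical voxel data and spacing.
#' @export
niftiRoundtrip <- function(x, path = tempfile(fileext = ".nii.gz"),
                           spacing = c(1, 1, 1)) {
  writeVolume(x, path, spacing)
  readVolume(path)
}
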