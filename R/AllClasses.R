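#' @import methods
NULL

#' UnitBallGrid: spherical coordinates for a voxel cube mapped into the unit ball
#'
#' Maps the voxel centers of an `N x N x N` cube onto the unit ball used by the
#' 3D Zernike basis. Two scalings are supported: `"cube_in_ball"` divides
#' centered coordinates by `sqrt(3) * (N - 1) / 2` so that every voxel center
#' (including the corners) lies inside the closed unit ball, and `"tight_fit"`
#' scales by the largest center-distance of an occupied voxel plus half a
#' voxel. Only voxels with radius at most 1 are retained.
#'
#' @slot cubeSide side length `N` of the cube (voxels).
#' @slot center geometric center of the cube, `(N - 1) / 2` per axis in
#'   0-based voxel coordinates.
#' @slot scaleRadius scaling radius in voxel units.
#' @slot scaling `"cube_in_ball"` or `"tight_fit"`.
#' @slot r,theta,phi spherical coordinates of the retained voxel centers
#'   (`theta` polar from +z, `phi` azimuth via `atan2`); at radius 0 the
#'   angles are set to 0 by convention.
#' @slot voxelIndex linear (1-based) indices of the retained voxels in the cube.
#' @slot voxelVolume unit-ball volume of one voxel, `(1 / scaleRadius)^3`.
#'
#' @seealso [buildUnitBallGrid()]
#' @export
setClass("UnitBallGrid",
  representation(
    cubeSide = "integer",
    center = "numeric",
    scaleRadius = "numeric",
    scaling = "character",
    r = "numeric",
    theta = "numeric",
    phi = "numeric",
    voxelIndex = "integer",
    voxelVolume = "numeric"
  )
)

setValidity("UnitBallGrid", function(object) {
  msg <- character()
  if (object@cubeSide < 2L) msg <- c(msg, "cubeSide must be >= 2")
  if (!isTRUE(all.equal(object@center, rep((object@cubeSide - 1) / 2, 3))))
    msg <- c(msg, "center must be (cubeSide - 1)/2 per axis")
  if (any(object@r < 0) || any(object@r > 1))
    msg <- c(msg, "all radii must lie in [0, 1]")
  if (!isTRUE(all.equal(object@voxelVolume, (1 / object@scaleRadius)^3)))
    msg <- c(msg, "voxelVolume must equal (1/scaleRadius)^3")
  if (length(object@r) != length(object@voxelIndex) ||
      length(object@r) != length(object@theta) ||
      length(object@r) != length(object@phi))
    msg <- c(msg, "r, theta, phi, voxelIndex must have equal length")
  if (length(msg)) msg else TRUE
})

#' ZernikeMoments: real 3D Zernike expansion coefficients
#'
#' Real coefficients `Z_nl^m` of a voxelized scalar field expanded over the
#' orthonormal 3D Zernike basis on the unit ball, for all valid `(n, l, m)`
#' triples with `n <= maxOrder`, `l <= n`, `n - l` even and `-l <= m <= l`,
#' stored in lexicographic `(n, l, m)` order.
#'
#' @slot maxOrder maximum expansion order.
#' @slot n,l,m integer index vectors, one entry per coefficient.
#' @slot values real coefficient values.
#' @slot grid the [UnitBallGrid-class] the moments were computed on.
#'
#' @seealso [zernikeMoments()], [zernikeDescriptor()], [reconstruct()]
#' @export
setClass("ZernikeMoments",
  representation(
    maxOrder = "integer",
    n = "integer",
    l = "integer",
    m = "integer",
    values = "numeric",
    grid = "UnitBallGrid"
  )
)

setValidity("ZernikeMoments", function(object) {
  msg <- character()
  if (length(object@values) != length(object@n) ||
      length(object@n) != length(object@l) || length(object@l) != length(object@m))
    msg <- c(msg, "index vectors and values must have equal length")
  if (sum(object@m >= 0L) != momentCount(object@maxOrder))
    msg <- c(msg, "number of m >= 0 triples must equal momentCount(maxOrder)")
  if (any(object@l > object@n) || any((object@n - object@l) %% 2L != 0L) ||
      any(abs(object@m) > object@l))
    msg <- c(msg, "invalid (n, l, m) triple present")
  if (length(msg)) msg else TRUE
})

#' ZernikeDescriptor: rotation-invariant per-(n, l) moment norms
#'
#' The vector of l2 norms `||Z_nl|| = sqrt(sum_m Z_nl^m ^ 2)`, one entry per
#' valid `(n, l)` pair ordered by `n` ascending then `l` ascending. This
#' vector is invariant under 3D rotations of the input field and serves as
#' the shape feature of a lesion.
#'
#' @slot maxOrder maximum expansion order.
#' @slot n,l integer index vectors.
#' @slot values non-negative norms.
#' @export
setClass("ZernikeDescriptor",
  representation(
    maxOrder = "integer",
    n = "integer",
    l = "integer",
    values = "numeric"
  )
)

setValidity("ZernikeDescriptor", function(object) {
  msg <- character()
  if (any(object@values < 0)) msg <- c(msg, "descriptor entries must be >= 0")
  if (length(object@values) != descriptorDimension(object@maxOrder))
    msg <- c(msg, "length must equal descriptorDimension(maxOrder)")
  if (length(msg)) msg else TRUE
})

#' Lesion3D: one connected white-matter-hyperintensity component
#'
#' A single connected lesion extracted from a binary mask together with the
#' FLAIR intensities of its voxels.
#'
#' @slot subjectId subject identifier.
#' @slot lesionId integer lesion number within the subject.
#' @slot coords integer matrix (voxels x 3) of 1-based voxel indices.
#' @slot intensities voxel intensities, same order as `coords`.
#' @slot centroid unweighted mean of the voxel coordinates (1-based).
#' @slot volumeVoxels number of voxels.
#' @slot volumeMm3 physical volume, `volumeVoxels * prod(spacing)`.
#' @slot spacing voxel spacing in mm per axis.
#' @export
setClass("Lesion3D",
  representation(
    subjectId = "character",
    lesionId = "integer",
    coords = "matrix",
    intensities = "numeric",
    centroid = "numeric",
    volumeVoxels = "integer",
    volumeMm3 = "numeric",
    spacing = "numeric"
  )
)

setValidity("Lesion3D", function(object) {
  msg <- character()
  if (ncol(object@coords) != 3L) msg <- c(msg, "coords must have 3 columns")
  if (object@volumeVoxels != nrow(object@coords))
    msg <- c(msg, "volumeVoxels must equal nrow(coords)")
  if (nrow(object@coords) != length(object@intensities))
    msg <- c(msg, "one intensity per voxel required")
  if (!isTRUE(all.equal(object@volumeMm3,
                        object@volumeVoxels * prod(object@spacing))))
    msg <- c(msg, "volumeMm3 must equal volumeVoxels * voxel volume")
  if (length(msg)) msg else TRUE
})

#' FuzzyHistogram: unit-sum fuzzy intensity histogram
#'
#' Texture feature of a lesion: each normalized intensity splits its unit
#' mass linearly between the two bins whose centers bracket it, and the final
#' histogram is divided by the number of contributing voxels so that the
#' frequencies sum to one.
#'
#' @slot nBins number of bins.
#' @slot frequencies non-negative frequencies summing to 1.
#' @slot lesionId provenance identifier.
#' @export
setClass("FuzzyHistogram",
  representation(
    nBins = "integer",
    frequencies = "numeric",
    lesionId = "character"
  )
)

setValidity("FuzzyHistogram", function(object) {
  msg <- character()
  if (length(object@frequencies) != object@nBins)
    msg <- c(msg, "length of frequencies must equal nBins")
  if (any(object@frequencies < 0)) msg <- c(msg, "frequencies must be >= 0")
  if (abs(sum(object@frequencies) - 1) > 1e-12)
    msg <- c(msg, "frequencies must sum to 1 within 1e-12")
  if (length(msg)) msg else TRUE
})

#' PenumbraLayers: one-voxel-thick dilation shells around a lesion
#'
#' The penumbra of a lesion decomposed into `nLayers` one-voxel-thick shells:
#' layer `i` holds the voxels added by the i-th morphological dilation,
#' excluding voxels that belong to any lesion and voxels outside the image.
#' Layer weights increase linearly outward, `w_i = i / sum(1..l)`.
#'
#' @slot nLayers number of shells `l`.
#' @slot layerVoxels list of linear voxel index vectors, one per shell.
#' @slot layerSizes shell sizes `V_i`.
#' @slot growthCounts supra-threshold voxel counts `GV_i`
#'   (`NA` until [countGrowthVoxels()] is applied).
#' @slot weights layer weights `w_i`.
#' @slot gamma threshold multiplier used for the growth counts (`NA` before).
#' @slot dim dimensions of the image grid the indices refer to.
#' @export
setClass("PenumbraLayers",
  representation(
    nLayers = "integer",
    layerVoxels = "list",
    layerSizes = "integer",
    growthCounts = "integer",
    weights = "numeric",
    gamma = "numeric",
    dim = "integer"
  )
)

setValidity("PenumbraLayers", function(object) {
  msg <- character()
  l <- object@nLayers
  if (length(object@layerVoxels) != l || length(object@layerSizes) != l ||
      length(object@weights) != l || length(object@growthCounts) != l)
    msg <- c(msg, "per-layer slots must have length nLayers")
  if (anyDuplicated(unlist(object@layerVoxels)))
    msg <- c(msg, "layers must be pairwise disjoint")
  if (!isTRUE(all.equal(object@weights, seq_len(l) / sum(seq_len(l)))))
    msg <- c(msg, "weights must equal i / sum(1..l)")
  gv <- object@growthCounts
  ok <- !is.na(gv)
  if (any(gv[ok] < 0L) || any(gv[ok] > object@layerSizes[ok]))
    msg <- c(msg, "growth counts must satisfy 0 <= GV_i <= V_i")
  if (length(msg)) msg else TRUE
})

#' PGIResult: Potential Growth Index of one lesion
#'
#' @slot lesionId lesion identifier.
#' @slot pgi the index, in `[0, 1]`.
#' @slot gamma,nLayers parameters used.
#' @slot layerSizes,growthCounts,weights per-layer breakdown.
#' @export
setClass("PGIResult",
  representation(
    lesionId = "character",
    pgi = "numeric",
    gamma = "numeric",
    nLayers = "integer",
    layerSizes = "integer",
    growthCounts = "integer",
    weights = "numeric"
  )
)

setValidity("PGIResult", function(object) {
  msg <- character()
  if (object@pgi < 0 || object@pgi > 1) msg <- c(msg, "PGI must lie in [0, 1]")
  expected <- sum(object@growthCounts * object@weights) / sum(object@layerSizes)
  if (!isTRUE(all.equal(object@pgi, expected)))
    msg <- c(msg, "PGI must equal sum(GV_i * w_i) / V_l")
  if (length(msg)) msg else TRUE
})

#' GapCurve: gap-statistic curve and selected cluster count
#'
#' Per-k within-cluster dispersion of the data, mean log dispersion of the
#' uniform reference sets, the gap values and their standard errors, and the
#' selected number of clusters.
#'
#' @slot k candidate cluster counts `1..N`.
#' @slot Wk within-cluster dispersion of the data at each k.
#' @slot logWkbMean mean of `log(W*_kb)` over the B reference sets.
#' @slot gap gap values.
#' @slot sdk per-k standard deviation of `log(W*_kb)`.
#' @slot sk `sdk * sqrt(1 + 1/B)`.
#' @slot kHat selected cluster count.
#' @slot B,N reference-set count and maximum k.
#' @export
setClass("GapCurve",
  representation(
    k = "integer",
    Wk = "numeric",
    logWkbMean = "numeric",
    gap = "numeric",
    sdk = "numeric",
    sk = "numeric",
    kHat = "integer",
    B = "integer",
    N = "integer"
  )
)

setValidity("GapCurve", function(object) {
  msg <- character()
  if (!isTRUE(all.equal(object@sk, object@sdk * sqrt(1 + 1 / object@B))))
    msg <- c(msg, "sk must equal sdk * sqrt(1 + 1/B)")
  if (object@kHat < 1L || object@kHat > object@N)
    msg <- c(msg, "kHat must lie in [1, N]")
  if (length(msg)) msg else TRUE
})

#' ClusterModel: a fitted K-means partition
#'
#' @slot k number of clusters.
#' @slot assignments per-row cluster labels.
#' @slot centroids k x p centroid matrix.
#' @slot Wk within-cluster dispersion, `sum_r sum_{x in C_r} ||x - xbar_r||^2`.
#' @export
setClass("ClusterModel",
  representation(
    k = "integer",
    assignments = "integer",
    centroids = "matrix",
    Wk = "numeric"
  )
)

setValidity("ClusterModel", function(object) {
  msg <- character()
  if (nrow(object@centroids) != object@k)
    msg <- c(msg, "one centroid per cluster required")
  if (any(is.na(object@assignments)) || any(object@assignments < 1L) ||
      any(object@assignments > object@k))
    msg <- c(msg, "every row must be assigned to a cluster in 1..k")
  if (length(msg)) msg else TRUE
})
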