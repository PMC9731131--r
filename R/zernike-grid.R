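#' Map a voxel cube into the unit ball
#'
#' Builds the spherical-coordinate grid used by the 3D Zernike transform.
#' Voxel centers are first centered on the cube's geometric center
#' (`(N - 1) / 2` per axis, 0-based) and then divided by a scaling radius.
#' With `scaling = "cube_in_ball"` (the default) the radius is
#' `sqrt(3) * (N - 1) / 2`, so the whole cube, corners included, lies inside
#' the closed unit ball. With `scaling = "tight_fit"` the radius is the
#' largest center-distance among the `occupied` voxels plus half a voxel,
#' which uses the ball's resolution more efficiently for compact objects;
#' voxels falling outside the ball are then dropped.
#'
#' @param cubeSide side length `N >= 2` of the cube, in voxels.
#' @param scaling `"cube_in_ball"` or `"tight_fit"`.
#' @param occupied for `"tight_fit"`, an integer matrix (voxels x 3) of
#'   1-based voxel indices of the occupied voxels; must be non-empty.
#' @return A [UnitBallGrid-class] object.
#' @examples
#' g <- buildUnitBallGrid(3)
#' max(g@r)  # the corner voxel sits exactly on the unit sphere
#' @export
buildUnitBallGrid <- function(cubeSide,
                              scaling = c("cube_in_ball", "tight_fit"),
                              occupied = NULL) {
  scaling <- match.arg(scaling)
  if (length(cubeSide) != 1L || is.na(cubeSide) || cubeSide < 2)
    stop("cubeSide must be a single integer >= 2")
  N <- as.integer(cubeSide)
  ctr <- (N - 1) / 2
  ax <- (0:(N - 1)) - ctr
  # first array index varies fastest in R's linear order
  dx <- rep(ax, times = N * N)
  dy <- rep(rep(ax, each = N), times = N)
  dz <- rep(ax, each = N * N)
  d <- sqrt(dx^2 + dy^2 + dz^2)
  if (scaling == "cube_in_ball") {
    Rsc <- sqrt(3) * (N - 1) / 2
  } else {
    if (is.null(occupied) || NROW(occupied) == 0L)
      stop("tight_fit requires a non-empty occupied voxel set")
    occ <- as.matrix(occupied)
    Rsc <- max(sqrt(rowSums((occ - 1 - ctr)^2))) + 0.5
  }
  r <- d / Rsc
  keep <- which(r <= 1 + 1e-12)
  r <- pmin(r[keep], 1)
  dzk <- dz[keep]
  theta <- ifelse(r > 0, acos(clamp(dzk / (r * Rsc), -1, 1)), 0)
  phi <- ifelse(r > 0, atan2(dy[keep], dx[keep]), 0)
  new("UnitBallGrid",
      cubeSide = N, center = rep(ctr, 3), scaleRadius = Rsc,
      scaling = scaling, r = r, theta = theta, phi = phi,
      voxelIndex = keep, voxelVolume = (1 / Rsc)^3)
}

#' @describeIn buildUnitBallGrid compact display
#' @param object a `UnitBallGrid`
#' @export
setMethod("show", "UnitBallGrid", function(object) {
  cat("UnitBallGrid:", object@cubeSide, "^3 cube,", object@scaling,
      sprintf("(scaleRadius = %.3f voxels, %d in-ball voxels)\n",
              object@scaleRadius, length(object@r)))
})
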