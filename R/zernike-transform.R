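#' Number of independent 3D Zernike moments up to order n
#'
#' Counts the `(n', l, m >= 0)` triples with `n' <= n`, `l <= n'`, `n' - l`
#' even: `sum_{i=0}^{n} floor((i + 2)^2 / 4)`.
#'
#' @param n maximum order (non-negative integer).
#' @return integer count.
#' @examples
#' momentCount(2)  # 7
#' @export
momentCount <- function(n) {
  if (any(n < 0)) stop("n must be >= 0")
  vapply(as.integer(n), function(ni) {
    i <- 0:ni
    as.integer(sum((i + 2L)^2 %/% 4L))
  }, integer(1))
}

#' Dimension of the Zernike shape descriptor
#'
#' Number of valid `(n', l)` pairs up to order `n`: `((n + 2) / 2)^2` for even
#' `n` and `(n + 3)(n + 1) / 4` for odd `n`.
#'
#' @param n maximum order (non-negative integer).
#' @return integer dimension.
#' @examples
#' descriptorDimension(100)  # 2601
#' descriptorDimension(250)  # 15876
#' @export
descriptorDimension <- function(n) {
  if (any(n < 0)) stop("n must be >= 0")
  vapply(as.integer(n), function(ni) {
    if (ni %% 2L == 0L) as.integer(((ni + 2L) / 2L)^2)
    else as.integer((ni + 3L) * (ni + 1L) / 4L)
  }, integer(1))
}

# shared streaming loop over harmonic degree l. For each l it yields the
# normalized Legendre block, the cos/sin azimuthal factors and the radial
# table evaluated at the unique radii, so forward and inverse transforms
# touch each basis value exactly once. Voxels are grouped by their (few
# hundred) unique radii, which is what makes order-100 transforms on 36^3
# cubes tractable.
zernikeContext <- function(grid, nmax) {
  r <- grid@r; theta <- grid@theta; phi <- grid@phi
  nvox <- length(r)
  ur <- sort(unique(r))
  list(
    nvox = nvox, ur = ur, gidx = match(r, ur),
    ct = cos(theta), st = sin(theta),
    Rtab = radialTablesByL(nmax, ur),
    cosm = azimuthTable(phi, nmax, cos), sinm = azimuthTable(phi, nmax, sin)
  )
}

# cos(m phi), sin(m phi) for m = 0..mmax via the Chebyshev recurrence
azimuthTable <- function(phi, mmax, fun) {
  out <- matrix(0, length(phi), mmax + 1L)
  out[, 1L] <- if (identical(fun, cos)) 1 else 0
  if (mmax >= 1L) {
    out[, 2L] <- fun(phi)
    if (mmax >= 2L) {
      c1 <- cos(phi)
      for (m in 2:mmax) out[, m + 1L] <- 2 * c1 * out[, m] - out[, m - 1L]
    }
  }
  out
}

# real spherical harmonic block for degree l: nvox x (2l+1), columns m = -l..l
harmonicBlock <- function(l, P, ctx) {
  Yb <- matrix(0, ctx$nvox, 2L * l + 1L)
  Yb[, l + 1L] <- P[, 1L]
  if (l > 0L) for (m in 1:l) {
    Yb[, l + 1L + m] <- sqrt(2) * P[, m + 1L] * ctx$cosm[, m + 1L]
    Yb[, l + 1L - m] <- sqrt(2) * P[, m + 1L] * ctx$sinm[, m + 1L]
  }
  Yb
}

#' Forward 3D Zernike transform
#'
#' Computes the real 3D Zernike moments of a voxel cube:
#' `Z_nl^m = (2n + 3) * sum_voxels f * Y_l^m(theta, phi) * R_nl(r) * dV`,
#' the discrete Cartesian realization of the spherical inner product over
#' the unit ball, restricted to in-ball voxels. The voxel volume
#' element `dV = (1/scaleRadius)^3` is constant, so the sum is exact for
#' voxel-constant fields.
#'
#' @param cube 3D numeric array whose side matches `grid@cubeSide`.
#' @param grid a [UnitBallGrid-class]; defaults to the cube-in-ball mapping
#'   of the cube.
#' @param maxOrder maximum expansion order `n`.
#' @return A [ZernikeMoments-class] object with coefficients in
#'   lexicographic `(n, l, m)` order.
#' @seealso [zernikeDescriptor()], [reconstruct()]
#' @export
zernikeMoments <- function(cube, maxOrder, grid = NULL) {
  cube <- as.array(cube)
  if (length(dim(cube)) != 3L || length(unique(dim(cube))) != 1L)
    stop("cube must be a cubic 3D array")
  if (is.null(grid)) grid <- buildUnitBallGrid(dim(cube)[1])
  if (dim(cube)[1] != grid@cubeSide) stop("cube side does not match grid")
  if (maxOrder < 0) stop("maxOrder must be >= 0")
  nmax <- as.integer(maxOrder)
  fvals <- as.numeric(cube[grid@voxelIndex])
  ctx <- zernikeContext(grid, nmax)
  blocks <- vector("list", nmax + 1L)
  Pprev <- NULL; Pprev2 <- NULL
  for (l in 0:nmax) {
    P <- legendreStep(l, Pprev, Pprev2, ctx$ct, ctx$st)
    Yb <- harmonicBlock(l, P, ctx)
    S <- rowsum(Yb * fvals, ctx$gidx)         # unique-radius partial sums
    ns <- seq(l, nmax, by = 2)
    blocks[[l + 1L]] <- (ctx$Rtab[[l + 1L]] %*% S) *
      ((2 * ns + 3) * grid@voxelVolume)
    Pprev2 <- Pprev; Pprev <- P
    if (!all(is.finite(blocks[[l + 1L]])))
      stop("non-finite basis values at degree ", l, "; reduce maxOrder")
  }
  blocksToMoments(blocks, nmax, grid)
}

# assemble per-l blocks (rows n, cols m = -l..l) into lexicographic storage
blocksToMoments <- function(blocks, nmax, grid) {
  pairs <- validPairs(nmax)
  total <- sum(2L * pairs$l + 1L)
  n <- integer(total); l <- integer(total); m <- integer(total)
  values <- numeric(total)
  pos <- 0L
  for (i in seq_len(nrow(pairs))) {
    ni <- pairs$n[i]; li <- pairs$l[i]
    cnt <- 2L * li + 1L
    row <- match(ni, seq(li, nmax, by = 2))
    n[pos + seq_len(cnt)] <- ni
    l[pos + seq_len(cnt)] <- li
    m[pos + seq_len(cnt)] <- (-li):li
    values[pos + seq_len(cnt)] <- blocks[[li + 1L]][row, ]
    pos <- pos + cnt
  }
  new("ZernikeMoments", maxOrder = as.integer(nmax), n = n, l = l, m = m,
      values = values, grid = grid)
}

# inverse of blocksToMoments, truncated at order M
momentsToBlocks <- function(moments, M) {
  blocks <- vector("list", M + 1L)
  for (l in 0:M) {
    ns <- seq(l, M, by = 2)
    B <- matrix(0, length(ns), 2L * l + 1L)
    for (i in seq_along(ns)) {
      sel <- moments@n == ns[i] & moments@l == l
      B[i, ] <- moments@values[sel]   # already ordered m = -l..l
    }
    blocks[[l + 1L]] <- B
  }
  blocks
}

#' Rotation-invariant Zernike shape descriptor
#'
#' Collapses the moments to the vector of per-(n, l) norms
#' `||Z_nl|| = sqrt(sum_{m=-l}^{l} Z_nl^m ^ 2)`, ordered by `n` ascending
#' then `l` ascending. Because the real harmonic basis is orthonormal, this
#' vector is unchanged by any 3D rotation of the input.
#'
#' @param moments a [ZernikeMoments-class] object.
#' @return A [ZernikeDescriptor-class] object.
#' @export
zernikeDescriptor <- function(moments) {
  stopifnot(is(moments, "ZernikeMoments"))
  key <- moments@n * (moments@maxOrder + 1L) + moments@l
  agg <- rowsum(moments@values^2, key)
  ukey <- as.integer(rownames(agg))
  ord <- order(ukey)   # lexicographic (n, l)
  new("ZernikeDescriptor",
      maxOrder = moments@maxOrder,
      n = ukey[ord] %/% (moments@maxOrder + 1L),
      l = ukey[ord] %% (moments@maxOrder + 1L),
      values = sqrt(agg[ord]))
}

#' Reconstruct a field from its Zernike moments
#'
#' Evaluates the truncated expansion
#' `f_M = sum_{n <= M} sum_l sum_m Z_nl^m V_nl^m(r, theta, phi)` at every
#' in-ball voxel of the grid; voxels outside the ball are set to 0.
#'
#' @param moments a [ZernikeMoments-class] object.
#' @param maxOrder truncation order `M <= moments@maxOrder`.
#' @return 3D numeric array of side `grid@cubeSide`.
#' @export
reconstruct <- function(moments, maxOrder = moments@maxOrder) {
  stopifnot(is(moments, "ZernikeMoments"))
  M <- as.integer(maxOrder)
  if (M > moments@maxOrder) stop("maxOrder exceeds the available order")
  grid <- moments@grid
  ctx <- zernikeContext(grid, M)
  blocks <- momentsToBlocks(moments, M)
  f <- numeric(ctx$nvox)
  Pprev <- NULL; Pprev2 <- NULL
  for (l in 0:M) {
    P <- legendreStep(l, Pprev, Pprev2, ctx$ct, ctx$st)
    Yb <- harmonicBlock(l, P, ctx)
    Tm <- crossprod(ctx$Rtab[[l + 1L]], blocks[[l + 1L]])  # unique radii x m
    f <- f + rowSums(Yb * Tm[ctx$gidx, , drop = FALSE])
    Pprev2 <- Pprev; Pprev <- P
  }
  out <- array(0, rep(grid@cubeSide, 3L))
  out[grid@voxelIndex] <- f
  out
}

#' Reconstruction error rate of a binary shape
#'
#' Thresholds the reconstructed field at 0.5 and returns the size of the
#' symmetric difference with the original binary shape, divided by the
#' original foreground size.
#'
#' @param original binary 3D array (values 0/1) with at least one foreground
#'   voxel.
#' @param reconstructed real 3D array of the same shape.
#' @return non-negative error rate (0 for a perfect reconstruction; 2 when
#'   an equal-sized reconstruction is completely disjoint).
#' @export
reconstructionError <- function(original, reconstructed) {
  if (!identical(dim(original), dim(reconstructed)))
    stop("original and reconstructed must have the same shape")
  orig <- original > 0.5
  if (!any(orig)) stop("original has no foreground voxels")
  rec <- reconstructed >= 0.5
  sum(xor(orig, rec)) / sum(orig)
}

#' Reconstruction-error convergence sweep
#'
#' Reconstructs at each requested order from one set of moments and reports
#' the error rate against the original binary cube.
#'
#' @param original binary 3D array the moments were computed from.
#' @param moments a [ZernikeMoments-class] object.
#' @param orders orders to evaluate (each `<= moments@maxOrder`).
#' @return data.frame with columns `order` and `error`.
#' @export
reconstructionErrorSweep <- function(original, moments, orders) {
  err <- vapply(orders, function(M)
    reconstructionError(original, reconstruct(moments, M)), numeric(1))
  data.frame(order = as.integer(orders), error = err)
}

#' @describeIn zernikeMoments moments as a data.frame (columns n, l, m, value)
#' @export
momentsTable <- function(moments) {
  stopifnot(is(moments, "ZernikeMoments"))
  data.frame(n = moments@n, l = moments@l, m = moments@m,
             value = moments@values)
}

#' Serialize / read Zernike moments
#'
#' Writes the coefficients as CSV (one row per `(n, l, m)` with columns
#' `n, l, m, value`) plus a JSON sidecar holding the order, scaling mode and
#' scale radius, and reads the pair back.
#'
#' @param moments a [ZernikeMoments-class] object.
#' @param csvPath path of the CSV file; the JSON metadata is written next to
#'   it with extension `.json`.
#' @return `writeMoments` returns `csvPath` invisibly; `readMoments` returns
#'   a data.frame of coefficients with the metadata in attribute `meta`.
#' @export
writeMoments <- function(moments, csvPath) {
  utils::write.csv(momentsTable(moments), csvPath, row.names = FALSE)
  meta <- list(maxOrder = moments@maxOrder,
               scaling = moments@grid@scaling,
               scaleRadius = moments@grid@scaleRadius,
               cubeSide = moments@grid@cubeSide)
  jsonlite::write_json(meta, sub("\\.csv$", ".json", csvPath),
                       auto_unbox = TRUE, digits = NA)
  invisible(csvPath)
}

#' @rdname writeMoments
#' @export
readMoments <- function(csvPath) {
  tab <- utils::read.csv(csvPath)
  jsonPath <- sub("\\.csv$", ".json", csvPath)
  meta <- if (file.exists(jsonPath)) jsonlite::read_json(jsonPath) else NULL
  structure(tab, meta = meta)
}

#' @describeIn zernikeMoments compact display
#' @param object a `ZernikeMoments`
#' @export
setMethod("show", "ZernikeMoments", function(object) {
  cat("ZernikeMoments: order", object@maxOrder, "-",
      length(object@values), "coefficients (",
      momentCount(object@maxOrder), "independent ) on a",
      object@grid@cubeSide, "^3 grid\n")
})

#' @describeIn zernikeDescriptor compact display
#' @param object a `ZernikeDescriptor`
#' @export
setMethod("show", "ZernikeDescriptor", function(object) {
  cat("ZernikeDescriptor: order", object@maxOrder, "-",
      length(object@values), "rotation-invariant entries\n")
})
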