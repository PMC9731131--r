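# Independent oracles and shared fixtures for the test suite.

# --- Jacobi-polynomial oracle for the radial functions -----------------------
# Direct evaluation of R_nl(r) = r^l P_k^{(0, l+1/2)}(2 r^2 - 1), k = (n-l)/2,
# through the explicit Jacobi sum: an algebraic route fully independent of the
# package's three-term recursion.
jacobiSum <- function(k, a, b, x) {
  s <- 0
  for (j in 0:k)
    s <- s + choose(k + a, k - j) * choose(k + b, j) *
         ((x - 1) / 2)^j * ((x + 1) / 2)^(k - j)
  s
}
radialOracle <- function(n, l, r) {
  r^l * jacobiSum((n - l) / 2, 0, l + 1 / 2, 2 * r^2 - 1)
}

# --- brute-force index enumeration -------------------------------------------
enumerateTriples <- function(nmax) {   # (n, l, m >= 0) triples
  cnt <- 0L
  for (n in 0:nmax) for (l in seq(n %% 2L, n, by = 2L)) cnt <- cnt + l + 1L
  cnt
}
enumeratePairs <- function(nmax) {     # (n, l) pairs
  cnt <- 0L
  for (n in 0:nmax) cnt <- cnt + length(seq(n %% 2L, n, by = 2L))
  cnt
}

# --- the 24 orientation-preserving cube rotations ----------------------------
# as (axis permutation, sign flips) pairs with determinant +1
cubeRotations <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  out <- list()
  for (p in perms) for (sx in c(1, -1)) for (sy in c(1, -1)) for (sz in c(1, -1)) {
    R <- matrix(0, 3, 3)
    s <- c(sx, sy, sz)
    for (i in 1:3) R[i, p[i]] <- s[i]
    if (abs(det(R) - 1) < 1e-9) out[[length(out) + 1L]] <- list(perm = p, sign = s)
  }
  out
}

rotateCube <- function(a, rot) {
  b <- aperm(a, rot$perm)
  if (rot$sign[1] < 0) b <- b[dim(b)[1]:1, , , drop = FALSE]
  if (rot$sign[2] < 0) b <- b[, dim(b)[2]:1, , drop = FALSE]
  if (rot$sign[3] < 0) b <- b[, , dim(b)[3]:1, drop = FALSE]
  array(b, dim(a))
}

# --- small geometric fixtures -------------------------------------------------
# binary ellipsoid (optionally rotated) in an N^3 cube centred on the grid
ellipsoidCube <- function(N, radii, rotation = NULL, shiftCenter = c(0, 0, 0)) {
  ctr <- (N - 1) / 2 + 1 + shiftCenter
  g <- as.matrix(expand.grid(x = 1:N, y = 1:N, z = 1:N))
  p <- sweep(g, 2, ctr)
  if (!is.null(rotation)) p <- p %*% rotation
  inside <- (p[, 1] / radii[1])^2 + (p[, 2] / radii[2])^2 +
            (p[, 3] / radii[3])^2 <= 1
  array(as.numeric(inside), c(N, N, N))
}

# smooth (C^1) radially decaying blob for resampling-based rotation tests
smoothBlobCube <- function(N, radii, rotation = NULL) {
  ctr <- (N - 1) / 2 + 1
  g <- as.matrix(expand.grid(x = 1:N, y = 1:N, z = 1:N))
  p <- sweep(g, 2, ctr)
  if (!is.null(rotation)) p <- p %*% rotation
  q <- (p[, 1] / radii[1])^2 + (p[, 2] / radii[2])^2 + (p[, 3] / radii[3])^2
  array(pmax(0, 1 - q)^2, c(N, N, N))
}

rotationMatrix <- function(ax, ay, az) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  Ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  Rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# mean silhouette width for known labels (O(n^2), test-sized inputs only)
silhouetteMean <- function(x, labels) {
  d <- as.matrix(dist(x))
  n <- nrow(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(d[i, labels == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# 12-lesion two-subject synthetic cohort used by the pipeline tests
testCohort <- function() {
  mkSubject <- function(seed) {
    centers <- list(c(14, 14, 14), c(14, 40, 14), c(14, 62, 40),
                    c(40, 14, 40), c(48, 48, 20), c(56, 20, 58))
    sc <- 1 + 0.12 * (seed %% 3)
    shapes <- list(
      list(type = "ellipsoid", radii = sc * c(3, 2.5, 2)),
      list(type = "ellipsoid", radii = sc * c(6, 2, 2)),
      list(type = "torus", R = 5 * sc, r = 1.6),
      list(type = "blob"),
      list(type = "ellipsoid", radii = sc * c(5, 4.5, 4)),
      list(type = "ellipsoid", radii = sc * c(2.5, 2.5, 2.5)))
    lesions <- lapply(seq_along(centers), function(i) {
      sh <- shapes[[i]]; ctr <- centers[[i]]
      gf <- c(0.9, 0.7, 0.5, 0.3, 0.1)[((i + seed) %% 5) + 1]
      if (sh$type == "blob") {
        list(type = "blob", center = ctr,
             spheres = cbind(c(ctr[1], ctr[1] + 3), c(ctr[2], ctr[2] + 2),
                             c(ctr[3], ctr[3] - 2), c(3, 2.2)),
             growthFractions = gf)
      } else c(sh, list(center = ctr, growthFractions = gf))
    })
    phantomSpec(dim = c(72, 72, 72), lesions = lesions, seed = seed)
  }
  ph1 <- makePhantom(mkSubject(11))
  ph2 <- makePhantom(mkSubject(22))
  list(
    manifest = list(
      list(subject = "s1", volume = ph1$volume, mask = ph1$mask),
      list(subject = "s2", volume = ph2$volume, mask = ph2$mask)),
    phantoms = list(s1 = ph1, s2 = ph2))
}

deskConfig <- function(seed = 3) {
  pipelineConfig(
    smallTarget = list(volume = 80, cube = 24, order = 16),
    largeTarget = list(volume = 200, cube = 28, order = 16),
    cutoffVoxels = 150,
    gapN = 5, gapB = 5, gapTrials = 20, gapRefTrials = 10,
    kmeansTrials = 50, seed = seed)
}
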