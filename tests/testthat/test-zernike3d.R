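test_that("unit-ball grid maps the cube as specified", {
  g <- buildUnitBallGrid(3)
  # corner voxel sits exactly on the unit sphere, center voxel at the origin
  expect_equal(max(g@r), 1)
  ctr <- which(g@r == 0)
  expect_length(ctr, 1)
  expect_equal(g@theta[ctr], 0)
  expect_equal(g@phi[ctr], 0)
  expect_equal(buildUnitBallGrid(36)@scaleRadius, sqrt(3) * 17.5,
               tolerance = 1e-12)
  expect_equal(g@voxelVolume, (1 / g@scaleRadius)^3)

  # tight_fit: scale radius is the max occupied distance plus half a voxel
  occ <- rbind(c(2, 2, 2), c(3, 2, 2))
  gt <- buildUnitBallGrid(3, "tight_fit", occ)
  expect_equal(gt@scaleRadius, 1.5)
  expect_true(all(gt@r <= 1))

  expect_error(buildUnitBallGrid(1), "cubeSide")
  expect_error(buildUnitBallGrid(5, "tight_fit"), "occupied")
})

test_that("normalized associated Legendre functions match closed forms and are orthonormal", {
  P <- normalizedAssocLegendre(0, c(-0.5, 0, 0.9))
  expect_equal(unname(P[, 1]), rep(sqrt(1 / (4 * pi)), 3))

  # degree 1, order 0 at x = 1 equals sqrt(3/(4 pi))
  P1 <- normalizedAssocLegendre(1, 1)
  i10 <- which(attr(P1, "l") == 1 & attr(P1, "m") == 0)
  expect_equal(P1[1, i10], sqrt(3 / (4 * pi)), tolerance = 1e-12)

  # orthonormality over the sphere: int P~_l^m P~_l'^m dx = delta_ll'/(2 pi)
  gl <- pracma::gaussLegendre(200, -1, 1)
  P <- normalizedAssocLegendre(12, gl$x)
  lidx <- attr(P, "l"); midx <- attr(P, "m")
  for (m in 0:4) {
    cols <- which(midx == m)
    G <- t(P[, cols]) %*% (P[, cols] * gl$w)
    expect_equal(unname(G), diag(1 / (2 * pi), length(cols)),
                 tolerance = 1e-10)
  }
  expect_error(normalizedAssocLegendre(3, 1.2), "\\[-1, 1\\]")
})

test_that("real spherical harmonics are orthonormal on the sphere", {
  # constant mode and vanishing sine term
  Y <- realSphericalHarmonics(1, c(0.3, 1.2), c(0, 0))
  expect_equal(unname(Y[, 1]), rep(sqrt(1 / (4 * pi)), 2))
  iNeg <- which(attr(Y, "l") == 1 & attr(Y, "m") == -1)
  expect_equal(unname(Y[, iNeg]), c(0, 0))

  # quadrature: Gauss-Legendre in cos(theta), uniform in phi
  gl <- pracma::gaussLegendre(64, -1, 1)
  nphi <- 128
  phi <- (seq_len(nphi) - 0.5) * 2 * pi / nphi
  th <- acos(gl$x)
  grid <- expand.grid(t = seq_along(th), p = phi)
  Y <- realSphericalHarmonics(8, th[grid$t], grid$p)
  w <- gl$w[grid$t] * (2 * pi / nphi)
  G <- t(Y) %*% (Y * w)
  expect_lt(max(abs(G - diag(ncol(Y)))), 1e-10)
})

test_that("radial polynomials agree with the Jacobi closed form", {
  r <- seq(0, 1, length.out = 41)
  R <- radialPolynomials(12, r)
  ns <- attr(R, "n"); ls <- attr(R, "l")
  for (i in seq_along(ns))
    expect_equal(unname(R[i, ]), radialOracle(ns[i], ls[i], r),
                 tolerance = 1e-12, label = sprintf("R_%d,%d", ns[i], ls[i]))

  # printed special cases
  expect_equal(unname(R[ns == 0 & ls == 0, ]), rep(1, 41))
  R20 <- unname(R[ns == 2 & ls == 0, ])
  expect_equal(R20, 2.5 * r^2 - 1.5, tolerance = 1e-12)
  expect_equal(R20[c(1, 41)], c(-1.5, 1))
  expect_error(radialPolynomials(4, 1.1), "\\[0, 1\\]")
})

test_that("moment counts and descriptor dimensions match brute-force enumeration", {
  expect_identical(momentCount(0), 1L)
  expect_identical(momentCount(2), 7L)
  expect_identical(momentCount(4), 22L)
  expect_identical(descriptorDimension(1), 2L)
  for (n in c(0:12, 37, 100, 161, 250, 300)) {
    expect_identical(momentCount(n), enumerateTriples(n))
    expect_identical(descriptorDimension(n), enumeratePairs(n))
  }
  expect_error(momentCount(-1))
  expect_error(descriptorDimension(-2))
})

test_that("forward transform of simple fields matches closed-form moments", {
  # zero field -> zero moments
  z0 <- zernikeMoments(array(0, c(8, 8, 8)), 4)
  expect_true(all(z0@values == 0))

  # constant 1 on a voxelized ball: Z_000 -> sqrt(4 pi), others -> 0
  N <- 48
  ctr <- (N - 1) / 2
  occ <- as.matrix(expand.grid(1:N, 1:N, 1:N))
  inside <- sqrt(rowSums((occ - 1 - ctr)^2)) <= ctr
  g <- buildUnitBallGrid(N, "tight_fit", occ[inside, ])
  ball <- array(0, c(N, N, N)); ball[g@voxelIndex] <- 1  # all in-ball voxels
  zm <- zernikeMoments(ball, 4, g)
  expect_equal(zm@values[1], sqrt(4 * pi), tolerance = 0.01)
  expect_lt(max(abs(zm@values[-1])), 0.05)

  # order-0 reconstruction of the constant ball is ~1 inside
  f0 <- reconstruct(zm, 0)
  expect_equal(mean(f0[ball == 1]), 1, tolerance = 0.05)

  expect_error(zernikeMoments(array(0, c(4, 4, 4)), 2, buildUnitBallGrid(6)),
               "match")
})

test_that("descriptor collapses moments to per-(n,l) norms", {
  zm <- zernikeMoments(array(0, c(6, 6, 6)), 4)
  d0 <- zernikeDescriptor(zm)
  expect_true(all(d0@values == 0))
  expect_length(d0@values, descriptorDimension(4))

  # a single nonzero moment appears as its own norm
  zm@values[zm@n == 2 & zm@l == 0 & zm@m == 0] <- 5
  d <- zernikeDescriptor(zm)
  expect_equal(d@values[d@n == 2 & d@l == 0], 5)
  expect_true(all(d@n >= d@l) && all((d@n - d@l) %% 2 == 0))
})

test_that("descriptors are invariant under axis-aligned cube rotations", {
  cube <- ellipsoidCube(20, c(6, 4, 2.5), shiftCenter = c(1, 0, -1))
  base <- zernikeDescriptor(zernikeMoments(cube, 10))@values
  for (rot in cubeRotations()[c(2, 8, 14, 23)]) {
    d <- zernikeDescriptor(zernikeMoments(rotateCube(cube, rot), 10))@values
    expect_lt(max(abs(d - base)), 1e-9)
  }
})

test_that("descriptors survive arbitrary rotation with tricubic resampling", {
  N <- 28
  radii <- c(8, 5.5, 4)
  f <- smoothBlobCube(N, radii)
  R <- rotationMatrix(0.4, -0.7, 1.1)
  fr <- smoothBlobCube(N, radii, rotation = R)  # exact rotated field
  d1 <- zernikeDescriptor(zernikeMoments(f, 12))@values
  d2 <- zernikeDescriptor(zernikeMoments(fr, 12))@values
  expect_lt(sqrt(sum((d1 - d2)^2)) / sqrt(sum(d1^2)), 0.02)

  # same comparison through the package's own tricubic resampler
  ctr <- rep((N - 1) / 2 + 1, 3)
  g <- as.matrix(expand.grid(x = 1:N, y = 1:N, z = 1:N))
  pts <- sweep(sweep(g, 2, ctr) %*% R, 2, ctr, "+")
  fres <- array(wmh3d:::interp3d(f, pts, "tricubic"), c(N, N, N))
  d3 <- zernikeDescriptor(zernikeMoments(fres, 12))@values
  expect_lt(sqrt(sum((d1 - d3)^2)) / sqrt(sum(d1^2)), 0.02)
})

test_that("reconstruction reproduces simple fields and flags bad input", {
  cube <- ellipsoidCube(16, c(5, 4, 3))
  zm <- zernikeMoments(cube, 20)
  expect_error(reconstruct(zm, 25), "exceeds")

  # self-consistency: binary cube recovered at matching order
  rec <- reconstruct(zm)
  expect_lt(reconstructionError(cube, rec), 0.25)

  # trivial error-rate cases
  expect_equal(reconstructionError(cube, cube), 0)
  disjoint <- array(0, dim(cube))
  disjoint[cube == 0][seq_len(sum(cube))] <- 1
  expect_equal(reconstructionError(cube, disjoint), 2)
  expect_error(reconstructionError(array(0, c(4, 4, 4)), array(0, c(4, 4, 4))),
               "foreground")
})

test_that("moment serialization round-trips through CSV + JSON", {
  zm <- zernikeMoments(ellipsoidCube(10, c(3, 2, 2)), 6)
  path <- file.path(tempdir(), "moments.csv")
  writeMoments(zm, path)
  back <- readMoments(path)
  expect_equal(back$value, zm@values)
  expect_equal(back$n, zm@n)
  meta <- attr(back, "meta")
  expect_equal(meta$maxOrder, 6)
  expect_equal(meta$scaling, "cube_in_ball")
})
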