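# Basis functions of the 3D Zernike expansion: orthonormal real spherical
# harmonics Y_l^m(theta, phi) and radial polynomials R_nl(r).
#
# The associated Legendre recursion carries the full orthonormalization
# (including the sqrt(1/4pi)), which keeps every intermediate value O(1) and
# the recursion stable to degree 250 and beyond in double precision.

# one step of the normalized associated Legendre recursion: returns the
# matrix P_l^m (points x (l+1), m = 0..l) from the two previous degrees
legendreStep <- function(l, Pprev, Pprev2, ct, st) {
  if (l == 0L) return(matrix(sqrt(1 / (4 * pi)), length(ct), 1L))
  P <- matrix(0, length(ct), l + 1L)
  P[, l + 1L] <- sqrt((2 * l + 1) / (2 * l)) * st * Pprev[, l]       # diagonal
  P[, l] <- sqrt(2 * l + 1) * ct * Pprev[, l]                         # sub-diagonal
  if (l >= 2L) for (m in 0:(l - 2L)) {
    C <- sqrt((2 * l + 1) / ((l + m) * (l - m)))
    C1 <- C * sqrt(2 * l - 1)
    C2 <- C * sqrt((l + m - 1) * (l - m - 1) / (2 * l - 3))
    P[, m + 1L] <- C1 * ct * Pprev[, m + 1L] - C2 * Pprev2[, m + 1L]
  }
  P
}

#' Normalized associated Legendre functions
#'
#' Evaluates the fully normalized associated Legendre functions
#' `P~_l^m(x)` for `0 <= l <= lmax`, `0 <= m <= l`, by the stable three-step
#' recursion (diagonal, sub-diagonal, then general degree). The
#' normalization is the spherical-harmonics one: `P~_0^0 = sqrt(1/(4*pi))`
#' and `integral P~_l^m(cos theta)^2 sin theta dtheta = 1/(2*pi)`, so that
#' the complex harmonics `P~_l^m e^{i m phi}` are orthonormal on the sphere.
#'
#' @param lmax maximum degree (values remain finite well beyond 250).
#' @param x evaluation points in `[-1, 1]` (typically `cos(theta)`).
#' @return numeric matrix, `length(x)` rows and one column per `(l, m >= 0)`
#'   pair in order `(0,0), (1,0), (1,1), (2,0), ...`; attributes `l` and `m`
#'   give the per-column indices.
#' @examples
#' normalizedAssocLegendre(0, 0.3)[1, 1]  # sqrt(1/(4*pi))
#' @export
normalizedAssocLegendre <- function(lmax, x) {
  if (lmax < 0) stop("lmax must be >= 0")
  if (any(abs(x) > 1)) stop("x must lie in [-1, 1]")
  lmax <- as.integer(lmax)
  ct <- as.numeric(x)
  st <- sqrt(pmax(0, 1 - ct^2))
  cols <- (lmax + 1L) * (lmax + 2L) / 2L
  out <- matrix(0, length(ct), cols)
  lidx <- integer(cols); midx <- integer(cols)
  Pprev <- NULL; Pprev2 <- NULL
  pos <- 0L
  for (l in 0:lmax) {
    P <- legendreStep(l, Pprev, Pprev2, ct, st)
    out[, pos + seq_len(l + 1L)] <- P
    lidx[pos + seq_len(l + 1L)] <- l
    midx[pos + seq_len(l + 1L)] <- 0:l
    pos <- pos + l + 1L
    Pprev2 <- Pprev; Pprev <- P
  }
  structure(out, l = lidx, m = midx)
}

#' Real spherical harmonics
#'
#' Orthonormal real spherical harmonics: `Y_l^m = sqrt(2) * P~_l^m * cos(m phi)`
#' for `m > 0`, `Y_l^0 = P~_l^0`, and `Y_l^m = sqrt(2) * P~_l^|m| * sin(|m| phi)`
#' for `m < 0`. The `sqrt(2)` factor makes the real basis orthonormal on the
#' sphere, which is what makes the per-(n, l) moment norms rotation
#' invariant.
#'
#' @param lmax maximum degree.
#' @param theta,phi polar and azimuthal angles (equal length).
#' @return numeric matrix, one row per point and one column per `(l, m)` with
#'   `-l <= m <= l`, column order `(0,0), (1,-1), (1,0), (1,1), ...`;
#'   attributes `l` and `m` index the columns.
#' @export
realSphericalHarmonics <- function(lmax, theta, phi) {
  if (lmax < 0) stop("lmax must be >= 0")
  if (length(theta) != length(phi)) stop("theta and phi must have equal length")
  lmax <- as.integer(lmax)
  P <- normalizedAssocLegendre(lmax, cos(theta))
  pl <- attr(P, "l"); pm <- attr(P, "m")
  npts <- length(theta)
  cols <- (lmax + 1L)^2
  out <- matrix(0, npts, cols)
  lidx <- integer(cols); midx <- integer(cols)
  for (l in 0:lmax) {
    base <- l^2 + l + 1L   # column of m = 0
    out[, base] <- P[, which(pl == l & pm == 0L)]
    lidx[base] <- l; midx[base] <- 0L
    if (l > 0) for (m in 1:l) {
      pcol <- P[, which(pl == l & pm == m)]
      out[, base + m] <- sqrt(2) * pcol * cos(m * phi)
      out[, base - m] <- sqrt(2) * pcol * sin(m * phi)
      lidx[base + m] <- l; midx[base + m] <- m
      lidx[base - m] <- l; midx[base - m] <- -m
    }
  }
  structure(out, l = lidx, m = midx)
}

# radial tables grouped by l: element l+1 is the matrix R_nl(r) with one row
# per n = l, l+2, ..., nmax. This is the recursion the whole transform rests
# on; the coefficients are the Jacobi-recurrence ones for
# R_nl(r) = r^l P_k^{(0, l+1/2)}(2 r^2 - 1), k = (n - l)/2, which makes the
# family orthogonal with weight r^2 and R_nl(1) = 1.
radialTablesByL <- function(nmax, r) {
  out <- vector("list", nmax + 1L)
  r2 <- r * r
  for (l in 0:nmax) {
    ns <- seq(l, nmax, by = 2)
    M <- matrix(0, length(ns), length(r))
    M[1L, ] <- r^l
    if (length(ns) >= 2L) {
      n <- l + 2
      M[2L, ] <- (n + 0.5) * r^n - (n - 0.5) * r^(n - 2)
    }
    if (length(ns) >= 3L) for (i in 3:length(ns)) {
      n <- ns[i]
      K1 <- (2 * n - 1) * (2 * n + 1) / ((n - l) * (n + l + 1))
      K2 <- -(2 * n - 1) * ((2 * n + 1) * (2 * n - 3) + (2 * l + 1)^2) /
            (2 * (n - l) * (n + l + 1) * (2 * n - 3))
      K3 <- -(n - l - 2) * (n + l - 1) * (2 * n + 1) /
            ((n - l) * (n + l + 1) * (2 * n - 3))
      M[i, ] <- (K1 * r2 + K2) * M[i - 1L, ] + K3 * M[i - 2L, ]
    }
    out[[l + 1L]] <- M
  }
  out
}

#' 3D Zernike radial polynomials
#'
#' Evaluates `R_nl(r)` for all valid pairs (`l <= n`, `n - l` even) up to
#' `nmax` by the three-term recursion in `n` seeded with `R_nn = r^n` and
#' `R_{n,n-2} = (n + 1/2) r^n - (n - 1/2) r^{n-2}`. The family is orthogonal
#' on `[0, 1]` with weight `r^2`
#' (`integral R_nl R_n'l r^2 dr = delta_nn' / (2n + 3)`) and satisfies
#' `R_nl(1) = 1`; both properties are enforced by the test suite against a
#' direct Jacobi-polynomial evaluation.
#'
#' @param nmax maximum order.
#' @param r radii in `[0, 1]`.
#' @return numeric matrix with one row per `(n, l)` pair (ordered by `n`
#'   ascending then `l` ascending) and one column per radius; attributes `n`
#'   and `l` index the rows.
#' @export
radialPolynomials <- function(nmax, r) {
  if (nmax < 0) stop("nmax must be >= 0")
  r <- as.numeric(r)
  if (any(r < 0 | r > 1)) stop("r must lie in [0, 1]")
  nmax <- as.integer(nmax)
  tabs <- radialTablesByL(nmax, r)
  pairs <- validPairs(nmax)
  out <- matrix(0, nrow(pairs), length(r))
  for (i in seq_len(nrow(pairs))) {
    n <- pairs$n[i]; l <- pairs$l[i]
    out[i, ] <- tabs[[l + 1L]][match(n, seq(l, nmax, by = 2)), ]
  }
  structure(out, n = pairs$n, l = pairs$l)
}

# all valid (n, l) pairs up to nmax, n ascending then l ascending
validPairs <- function(nmax) {
  n <- integer(0); l <- integer(0)
  for (ni in 0:nmax) {
    li <- seq(ni %% 2L, ni, by = 2L)
    n <- c(n, rep(ni, length(li))); l <- c(l, li)
  }
  data.frame(n = n, l = l)
}
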