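# separable cubic-convolution (Keys, a = -1/2) and trilinear resampling of a
# 3D field at arbitrary points; used by the volume-normalization step and by
# the rotation-invariance checks

keysKernel <- function(t, a = -0.5) {
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

# pts: K x 3 matrix of 1-based continuous voxel coordinates; values outside
# the array are treated as 0
interp3d <- function(vol, pts, method = c("tricubic", "trilinear")) {
  method <- match.arg(method)
  dims <- dim(vol)
  K <- nrow(pts)
  out <- numeric(K)
  if (method == "tricubic") {
    i0 <- floor(pts)
    fr <- pts - i0
    offs <- -1:2
    w <- lapply(1:3, function(ax)
      vapply(offs, function(o) keysKernel(fr[, ax] - o), numeric(K)))
    for (ox in 1:4) for (oy in 1:4) for (oz in 1:4) {
      ix <- i0[, 1] + offs[ox]; iy <- i0[, 2] + offs[oy]; iz <- i0[, 3] + offs[oz]
      ok <- ix >= 1 & ix <= dims[1] & iy >= 1 & iy <= dims[2] & iz >= 1 & iz <= dims[3]
      if (!any(ok)) next
      lin <- (iz[ok] - 1) * dims[1] * dims[2] + (iy[ok] - 1) * dims[1] + ix[ok]
      out[ok] <- out[ok] + w[[1]][ok, ox] * w[[2]][ok, oy] * w[[3]][ok, oz] * vol[lin]
    }
  } else {
    i0 <- floor(pts)
    fr <- pts - i0
    for (ox in 0:1) for (oy in 0:1) for (oz in 0:1) {
      ix <- i0[, 1] + ox; iy <- i0[, 2] + oy; iz <- i0[, 3] + oz
      ok <- ix >= 1 & ix <= dims[1] & iy >= 1 & iy <= dims[2] & iz >= 1 & iz <= dims[3]
      if (!any(ok)) next
      wgt <- (if (ox) fr[, 1] else 1 - fr[, 1]) *
             (if (oy) fr[, 2] else 1 - fr[, 2]) *
             (if (oz) fr[, 3] else 1 - fr[, 3])
      lin <- (iz[ok] - 1) * dims[1] * dims[2] + (iy[ok] - 1) * dims[1] + ix[ok]
      out[ok] <- out[ok] + wgt[ok] * vol[lin]
    }
  }
  out
}
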