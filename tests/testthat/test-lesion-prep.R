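makeMaskPair <- function() {
  dims <- c(24, 24, 24)
  mask <- array(0, dims)
  mask[3:6, 3:6, 3:6] <- 1                       # 64 voxels > 30 mm^3
  mask[15:16, 15:19, 15] <- 1                    # 10 voxels, below the floor
  vol <- array(100, dims)
  vol[mask == 1] <- 150 + seq_len(sum(mask))
  list(volume = vol, mask = mask)
}

test_that("lesion extraction applies the strict volume floor", {
  fx <- makeMaskPair()
  les <- extractLesions(fx$volume, fx$mask, minVolumeMm3 = 30)
  expect_length(les, 1)
  expect_equal(les[[1]]@volumeVoxels, 64L)
  expect_equal(les[[1]]@volumeMm3, 64)
  expect_equal(les[[1]]@centroid, c(4.5, 4.5, 4.5))
  expect_length(les[[1]]@intensities, 64)

  # empty mask -> empty list; 27-voxel cube at the floor is excluded
  expect_length(extractLesions(fx$volume, array(0, dim(fx$mask))), 0)
  m27 <- array(0, c(10, 10, 10)); m27[4:6, 4:6, 4:6] <- 1
  expect_length(extractLesions(array(1, c(10, 10, 10)), m27, 30), 0)
  # ... but survives a smaller floor
  expect_length(extractLesions(array(1, c(10, 10, 10)), m27, 26), 1)

  expect_error(extractLesions(fx$volume, fx$mask[1:10, , ]), "shape")
  badMask <- fx$mask; badMask[1] <- 0.5
  expect_error(extractLesions(fx$volume, badMask), "binary")
})

test_that("connectivity setting separates diagonal components", {
  mask <- array(0, c(12, 12, 12))
  mask[3:4, 3:4, 3:4] <- 1
  mask[5, 5, 5] <- 1   # touches only diagonally
  vol <- array(1, dim(mask))
  expect_length(extractLesions(vol, mask, 0, connectivity = 26), 1)
  expect_length(extractLesions(vol, mask, 0, connectivity = 6), 2)
})

test_that("size grouping puts the boundary in the small group", {
  mk <- function(nv) {
    new("Lesion3D", subjectId = "s", lesionId = 1L,
        coords = cbind(seq_len(nv), 1L, 1L), intensities = rep(1, nv),
        centroid = c((nv + 1) / 2, 1, 1), volumeVoxels = as.integer(nv),
        volumeMm3 = nv, spacing = c(1, 1, 1))
  }
  grp <- splitBySize(list(mk(80), mk(250), mk(251)), 250)
  expect_equal(vapply(grp$small, function(x) x@volumeVoxels, integer(1)),
               c(80L, 250L))
  expect_equal(vapply(grp$large, function(x) x@volumeVoxels, integer(1)), 251L)
  allSmall <- splitBySize(list(mk(10), mk(250)), 250)
  expect_length(allSmall$large, 0)
})

test_that("volume rescaling hits the closest achievable count", {
  sphere <- ellipsoidCube(14, c(5, 5, 5))
  out <- rescaleToTargetVolume(sphere, 80)
  expect_lte(abs(sum(out) - 80), 3)   # closest achievable is within a few voxels

  # identity ratio keeps the volume within 2%
  same <- rescaleToTargetVolume(sphere, sum(sphere))
  expect_lte(abs(sum(same) - sum(sphere)) / sum(sphere), 0.02)

  # printed scaling-ratio arithmetic
  expect_equal((80 / 1000)^(1 / 3), 0.4308869, tolerance = 1e-6)

  # single voxel upscales by block replication
  one <- array(1, c(1, 1, 1))
  up <- rescaleToTargetVolume(one, 27)
  expect_equal(dim(up), c(3L, 3L, 3L))
  expect_true(all(up == 1))
})

test_that("rescale threshold search is optimal over observed values", {
  shape <- ellipsoidCube(12, c(4.5, 3.5, 2.5))
  target <- 60
  out <- rescaleToTargetVolume(shape, target)
  achieved <- abs(sum(out) - target)
  # oracle: every threshold over the interpolated values does no better
  v <- sum(shape)
  a <- (target / v)^(1 / 3)
  pad <- 2L
  padded <- array(0, dim(shape) + 4L)
  padded[3:(dim(shape)[1] + 2), 3:(dim(shape)[2] + 2), 3:(dim(shape)[3] + 2)] <- shape
  outDim <- pmax(3L, as.integer(ceiling(dim(shape) * a))) + 2L
  g <- as.matrix(expand.grid(x = seq_len(outDim[1]), y = seq_len(outDim[2]),
                             z = seq_len(outDim[3])))
  pts <- sweep(sweep(g, 2, (outDim + 1) / 2), 2, rep(1 / a, 3), "*")
  pts <- sweep(pts, 2, (dim(padded) + 1) / 2, "+")
  vals <- wmh3d:::interp3d(padded, pts, "tricubic")
  bestPossible <- min(abs(vapply(sort(unique(vals[vals > 0])),
                                 function(t) sum(vals >= t), numeric(1)) - target))
  expect_equal(achieved, bestPossible)
})

test_that("embedding centers the shape and preserves voxel count", {
  one <- array(1, c(1, 1, 1))
  cube <- embedInCube(one, 36)
  expect_equal(unname(which(cube == 1, arr.ind = TRUE)[1, ]), c(18, 18, 18))

  block <- array(1, c(3, 3, 3))
  emb <- embedInCube(block, 15)
  expect_equal(sum(emb), 27)
  cen <- colMeans(which(emb == 1, arr.ind = TRUE))
  expect_true(all(abs(cen - 8) <= 0.5))

  rod <- array(0, c(40, 3, 3)); rod[1:40, 2, 2] <- 1
  expect_error(embedInCube(rod, 36), "exceeds")
})

test_that("extraction and grouping are stable under volume translation", {
  fx <- makeMaskPair()
  les1 <- extractLesions(fx$volume, fx$mask, 30)
  shift <- function(a, s) {
    out <- array(0, dim(a))
    out[(1 + s):dim(a)[1], , ] <- a[1:(dim(a)[1] - s), , ]
    out
  }
  les2 <- extractLesions(shift(fx$volume, 4), shift(fx$mask, 4), 30)
  expect_equal(les2[[1]]@volumeVoxels, les1[[1]]@volumeVoxels)
  expect_equal(les2[[1]]@centroid - c(4, 0, 0), les1[[1]]@centroid)
  expect_equal(sort(les2[[1]]@intensities), sort(les1[[1]]@intensities))
})

test_that("lesion table summarizes size groups", {
  fx <- makeMaskPair()
  les <- extractLesions(fx$volume, fx$mask, 5)
  tab <- lesionTable(les, cutoffVoxels = 20)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$group, c("large", "small"))
  expect_named(lesionTable(list()),
               c("subject_id", "lesion_id", "volume_voxels", "volume_mm3",
                 "centroid_x", "centroid_y", "centroid_z", "group"))
})
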