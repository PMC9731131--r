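test_that("phantom primitives rasterize with the expected volumes", {
  sp <- phantomSpec(dim = c(24, 24, 24), lesions = list(
    list(type = "ellipsoid", center = c(12, 12, 12), radii = c(4, 3, 2))))
  ph <- makePhantom(sp)
  v <- ph$truth$lesions[[1]]$volumeVoxels
  expect_lt(abs(v - 4 / 3 * pi * 4 * 3 * 2) / (4 / 3 * pi * 24), 0.05)
  expect_equal(sum(ph$mask), v)

  # torus: one 26-connected component with a hole through its axis
  spT <- phantomSpec(dim = c(28, 28, 28), lesions = list(
    list(type = "torus", center = c(14, 14, 14), R = 6, r = 2)))
  phT <- makePhantom(spT)
  comps <- wmh3d:::labelComponents(phT$mask, 26L)
  expect_length(comps, 1)
  expect_equal(phT$mask[14, 14, 14], 0)        # axis voxel inside the hole
  expect_equal(phT$mask[14 + 6, 14, 14], 1)    # ring voxel
})

test_that("phantom generation is deterministic and overlap is rejected", {
  sp <- phantomSpec(dim = c(30, 30, 30), lesions = list(
    list(type = "ellipsoid", center = c(10, 10, 10), radii = c(3, 3, 2))),
    noiseSd = 2, seed = 17)
  a <- makePhantom(sp); b <- makePhantom(sp)
  expect_identical(a$volume, b$volume)
  expect_identical(a$mask, b$mask)

  bad <- phantomSpec(dim = c(30, 30, 30), lesions = list(
    list(type = "ellipsoid", center = c(10, 10, 10), radii = c(4, 4, 4)),
    list(type = "ellipsoid", center = c(12, 10, 10), radii = c(4, 4, 4))))
  expect_error(makePhantom(bad), "overlap")
})

test_that("ground truth predicts extraction and PGI exactly on noise-free phantoms", {
  sp <- phantomSpec(dim = c(40, 40, 40), lesions = list(
    list(type = "ellipsoid", center = c(12, 12, 12), radii = c(4, 3, 2),
         growthFractions = c(1, 0.75, 0.5, 0.25, 0)),
    list(type = "blob", center = c(30, 30, 28),
         spheres = cbind(c(30, 32), c(30, 30), c(27, 30), c(3, 2.5)),
         growthFractions = 0.4)), seed = 5)
  ph <- makePhantom(sp)
  les <- extractLesions(ph$volume, ph$mask, 0)
  expect_length(les, 2)
  ordTruth <- order(vapply(ph$truth$lesions, function(x) x$volumeVoxels, numeric(1)))
  ordFound <- order(vapply(les, function(x) x@volumeVoxels, integer(1)))
  for (i in seq_along(les)) {
    tr <- ph$truth$lesions[[ordTruth[i]]]
    fl <- les[[ordFound[i]]]
    expect_equal(fl@volumeVoxels, tr$volumeVoxels)
    expect_equal(fl@centroid, unname(tr$centroid))
  }
  # pooled stats from extraction match the generator's record
  st <- subjectIntensityStats(les)
  expect_equal(st$m, ph$truth$m)
  expect_equal(st$sigma, ph$truth$sigma)
  # layer sizes and growth counts match the Chebyshev-distance ground truth
  pgiTab <- subjectPGI(ph$volume, les, nLayers = 5, gamma = ph$truth$gamma)
  for (i in seq_along(les)) {
    tr <- ph$truth$lesions[[ordTruth[i]]]
    row <- pgiTab[pgiTab$lesion_id == les[[ordFound[i]]]@lesionId, ]
    expect_equal(unname(unlist(row[paste0("V_", 1:5)])), as.numeric(tr$layerSizes))
    expect_equal(unname(unlist(row[paste0("GV_", 1:5)])), as.numeric(tr$growthCounts))
    expect_equal(row$PGI, tr$pgi)
  }
})

test_that("blob features are well separated and reproducible", {
  x <- makeBlobFeatures(3, 50, separation = 10, dim = 2, seed = 6)
  expect_equal(dim(x), c(150L, 2L))
  expect_gt(silhouetteMean(x, attr(x, "labels")), 0.8)
  y <- makeBlobFeatures(3, 50, separation = 10, dim = 2, seed = 6)
  expect_identical(unclass(x), unclass(y))
  one <- makeBlobFeatures(1, 20, seed = 2)
  expect_equal(unique(attr(one, "labels")), 1L)
})

test_that("NIfTI round trip preserves voxels and spacing", {
  v <- withr::with_seed(8, array(runif(6 * 7 * 8), c(6, 7, 8)))
  back <- niftiRoundtrip(v)
  expect_equal(as.vector(back), as.vector(v))
  expect_equal(unname(RNifti::pixdim(back)[1:3]), c(1, 1, 1))

  # binary mask and anisotropic spacing survive
  m <- array(sample(0:1, 4^3, TRUE), c(4, 4, 4))
  back2 <- niftiRoundtrip(m, spacing = c(1, 1, 2))
  expect_equal(as.vector(back2), as.vector(m))
  expect_equal(unname(RNifti::pixdim(back2)[1:3]), c(1, 1, 2))

  expect_warning(writeVolume(v, "/nonexistent-dir/x.nii.gz"),
                 "cannot open")
})
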