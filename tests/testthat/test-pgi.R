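pointLesionLayers <- function(nLayers = 2, connectivity = 26, dims = c(15, 15, 15)) {
  mask <- array(FALSE, dims); mask[8, 8, 8] <- TRUE
  buildPenumbraLayers(mask, nLayers = nLayers, connectivity = connectivity)
}

test_that("subject statistics pool intensities with population SD", {
  expect_equal(subjectIntensityStats(c(2, 2, 2))[c("m", "sigma")],
               list(m = 2, sigma = 0))
  st <- subjectIntensityStats(c(1, 2, 3))
  expect_equal(st$m, 2)
  expect_equal(st$sigma, sqrt(2 / 3))
  # pooling, not per-lesion averaging
  mk <- function(f) new("Lesion3D", subjectId = "s", lesionId = 1L,
    coords = cbind(seq_along(f), 1L, 1L), intensities = f,
    centroid = c(mean(seq_along(f)), 1, 1), volumeVoxels = length(f),
    volumeMm3 = length(f) + 0.0, spacing = c(1, 1, 1))
  st2 <- subjectIntensityStats(list(mk(c(1, 1)), mk(c(3, 3))))
  expect_equal(st2$m, 2)
  expect_equal(st2$nVoxels, 4)
  expect_error(subjectIntensityStats(numeric(0)), "no lesion")
})

test_that("penumbra shells have the free-space dilation geometry", {
  pl <- pointLesionLayers(2, 26)
  expect_equal(pl@layerSizes, c(26L, 98L))       # 3^3-1 and 5^3-3^3
  expect_equal(pointLesionLayers(1, 6)@layerSizes, 6L)
  expect_equal(pl@weights, c(1, 2) / 3)

  # clipping at the image face shrinks the shells
  mask <- array(FALSE, c(15, 15, 15)); mask[1, 8, 8] <- TRUE
  plEdge <- buildPenumbraLayers(mask, nLayers = 2)
  expect_true(all(plEdge@layerSizes < c(26L, 98L)))

  # voxels of other lesions are excluded from the shells
  mask1 <- array(FALSE, c(15, 15, 15)); mask1[8, 8, 8] <- TRUE
  all2 <- mask1; all2[9, 8, 8] <- TRUE
  plExcl <- buildPenumbraLayers(mask1, all2, nLayers = 1)
  expect_equal(plExcl@layerSizes, 25L)

  expect_error(buildPenumbraLayers(array(FALSE, c(5, 5, 5))), "empty")
  expect_error(buildPenumbraLayers(all2, mask1), "contained")
})

test_that("layers partition the dilated region", {
  ph <- makePhantom(phantomSpec(dim = c(32, 32, 32), lesions = list(
    list(type = "ellipsoid", center = c(16, 15, 17), radii = c(4, 3, 2.5)))))
  mask <- ph$mask > 0
  pl <- buildPenumbraLayers(mask, nLayers = 3)
  dil <- mask
  for (i in 1:3) dil <- wmh3d:::dilateMask(dil, 26L)
  expect_equal(sum(pl@layerSizes), sum(dil & !mask))
  expect_false(anyDuplicated(unlist(pl@layerVoxels)) > 0)
})

test_that("growth counting thresholds at m - gamma * sigma", {
  pl <- pointLesionLayers(2)
  vol <- array(0, c(15, 15, 15))
  st <- list(m = 500, sigma = 10)

  # all supra-threshold
  vol[] <- 1000
  expect_equal(countGrowthVoxels(pl, vol, st)@growthCounts, c(26L, 98L))
  # all sub-threshold
  vol[] <- 0
  expect_equal(countGrowthVoxels(pl, vol, st)@growthCounts, c(0L, 0L))
  # exactly 6 supra-threshold voxels placed in layer 1
  vol[] <- 0
  vol[pl@layerVoxels[[1]][1:6]] <- st$m
  expect_equal(countGrowthVoxels(pl, vol, st)@growthCounts, c(6L, 0L))
  # boundary: f == m - gamma*sigma counts as growth
  vol[] <- st$m - 2.5 * st$sigma
  expect_equal(countGrowthVoxels(pl, vol, st, gamma = 2.5)@growthCounts,
               c(26L, 98L))
})

test_that("PGI matches hand-evaluated layer arithmetic", {
  # 6-connectivity point lesion: shells of 6 and 18 voxels
  pl6 <- pointLesionLayers(2, 6)
  expect_equal(pl6@layerSizes, c(6L, 18L))
  vol <- array(0, c(15, 15, 15))
  vol[pl6@layerVoxels[[1]]] <- 100
  res <- computePGI(countGrowthVoxels(pl6, vol, list(m = 100, sigma = 1)))
  expect_equal(res@pgi, 6 * (1 / 3) / 24, tolerance = 1e-12)

  # all-growth free-space point lesion, 26-connectivity
  pl <- pointLesionLayers(2, 26)
  vol[] <- 1e6
  resAll <- computePGI(countGrowthVoxels(pl, vol, list(m = 0, sigma = 1)))
  expect_equal(resAll@pgi, (26 * (1 / 3) + 98 * (2 / 3)) / 124, tolerance = 1e-12)

  # no growth voxels -> PGI 0
  vol[] <- -1e6
  expect_equal(computePGI(countGrowthVoxels(pl, vol, list(m = 0, sigma = 1)))@pgi, 0)

  expect_error(computePGI(pl), "growth counts")
})

test_that("PGI is monotone in gamma and bounded in [0, 1]", {
  ph <- makePhantom(phantomSpec(dim = c(36, 36, 36), lesions = list(
    list(type = "ellipsoid", center = c(18, 18, 18), radii = c(5, 4, 3),
         growthFractions = c(0.9, 0.7, 0.5, 0.3, 0.1))), seed = 2))
  les <- extractLesions(ph$volume, ph$mask, 30)
  mask <- ph$mask > 0
  st <- subjectIntensityStats(les)
  pl <- buildPenumbraLayers(mask, nLayers = 5)
  pgis <- vapply(c(0.5, 1, 2.5, 5, 50), function(g)
    computePGI(countGrowthVoxels(pl, ph$volume, st, g))@pgi, numeric(1))
  expect_true(all(diff(pgis) >= 0))
  expect_true(all(pgis >= 0 & pgis <= 1))
})

test_that("weights sum to one and increase outward", {
  for (l in c(1, 3, 5, 9)) {
    mask <- array(FALSE, c(25, 25, 25)); mask[13, 13, 13] <- TRUE
    pl <- buildPenumbraLayers(mask, nLayers = l)
    expect_equal(sum(pl@weights), 1, tolerance = 1e-14)
    if (l > 1) expect_true(all(diff(pl@weights) > 0))
  }
})

test_that("gamma = 2.5 corresponds to 99.38% one-sided Gaussian coverage", {
  expect_equal(round(100 * penumbraCoverage(2.5), 2), 99.38)
})
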