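test_that("voxel-to-world affine mapping", {
  expect_equal(voxelToWorld(c(3, 4, 5), diag(4)), c(3, 4, 5))
  aff <- diag(4); aff[1, 4] <- 10
  expect_equal(voxelToWorld(c(3, 4, 5), aff), c(13, 4, 5))
  ## round trip world -> voxel -> world under a random invertible affine
  set.seed(71)
  for (r in 1:5) {
    A <- diag(4)
    A[1:3, 1:3] <- matrix(rnorm(9), 3) + diag(3) * 3
    A[1:3, 4] <- rnorm(3, 0, 20)
    w <- rnorm(3, 0, 50)
    expect_equal(voxelToWorld(worldToVoxel(w, A), A), w, tolerance = 1e-9)
  }
  expect_error(voxelToWorld(c(1, 1, 1), matrix(0, 4, 4)), "singular")
})

test_that("component labelling agrees with a BFS oracle for all connectivities", {
  set.seed(73)
  for (rep in 1:6) {
    arr <- array(runif(15^3) < 0.25, c(15, 15, 15))
    for (conn in c("faces", "faces_edges", "faces_edges_corners")) {
      lab <- longsem:::.labelComponents(arr, conn)
      oracle <- bfsLabel(arr, conn)
      expect_identical(canonicalPartition(lab), canonicalPartition(oracle))
    }
  }
})

test_that("two-blob extent thresholding keeps only the larger cluster", {
  dm <- c(12, 12, 12)
  p <- array(1, dm); zarr <- array(0, dm)
  blob1 <- as.matrix(expand.grid(2:5, 2:5, 2:5))        # 64 voxels > 50
  blob2 <- as.matrix(expand.grid(8:11, 8:11, 8:10))[1:40, ]  # 40 voxels
  for (b in list(blob1, blob2)) {
    idx <- (b[, 3] - 1) * 144 + (b[, 2] - 1) * 12 + b[, 1]
    p[idx] <- 1e-5
    zarr[idx] <- 4
  }
  zarr[3, 3, 3] <- 7.5  # peak inside blob 1
  map <- new("StatMap", beta = zarr, z = zarr, p = p,
             converged = array(TRUE, dm), mask = array(TRUE, dm),
             affine = diag(4), meta = list(target = "slope"))
  cl <- thresholdCluster(map, pThresh = 0.001, minExtent = 50)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$size, 64)
  expect_equal(cl$peakZ, 7.5)
  expect_equal(unlist(cl[1, c("peakX", "peakY", "peakZ.mm")]), c(3, 3, 3),
               ignore_attr = TRUE)
  ## strict inequality: a cluster of exactly minExtent voxels is dropped
  cl2 <- thresholdCluster(map, pThresh = 0.001, minExtent = 64)
  expect_equal(nrow(cl2), 0)
  ## all-p-1 map: empty table, not an error
  map1 <- new("StatMap", beta = zarr, z = zarr, p = array(1, dm),
              converged = array(TRUE, dm), mask = array(TRUE, dm),
              affine = diag(4), meta = list())
  expect_equal(nrow(thresholdCluster(map1)), 0)
})

test_that("voxel mapping localizes a planted slope effect and masks correctly", {
  cfg <- smallConfig(n = 300, seed = 77, grid = c(12L, 12L, 12L),
                     maskRadiusVox = 5, effectCenter = c(6.5, 6.5, 6.5),
                     effectRadiusVox = 2.5, coupling = 0.9,
                     fwhmMm = 0, effectNoiseSD = 0.02,
                     backgroundNoiseSD = 0.08)
  panel <- genItemPanel(cfg)
  gen <- genVolumes(cfg, panel@meta$truth$slope)
  mi <- longsem:::.buildMeasurementSpec(12, 3, "shared", "shared")
  base <- buildLGCM(mi, growthSpec(), panel = panel)
  map <- mapVoxelPredictor(panel, gen$volumes, gen$mask, base,
                           target = "slope", affine = gen$affine, seed = 1)
  expect_s4_class(map, "StatMap")
  ## out-of-mask voxels are missing-coded everywhere
  expect_true(all(is.na(map@z[!gen$mask])))
  expect_true(all(is.na(map@p[!gen$mask])))
  ## global |z| peak falls inside the true effect region
  pk <- which.max(abs(map@z))
  expect_true(gen$truth[pk])
  ## betas inside the region are positive (coupling > 0, slope predictor)
  expect_gt(mean(map@beta[gen$truth & gen$mask], na.rm = TRUE), 0)
  ## ID mismatch is a hard error
  expect_error(mapVoxelPredictor(panel, gen$volumes[, , , 1:100], gen$mask, base),
               "ID mismatch")
})

test_that("fixed-measurement and full-refit modes agree on strong effects", {
  cfg <- smallConfig(n = 150, seed = 79, grid = c(6L, 6L, 6L),
                     maskRadiusVox = 1.2, effectCenter = c(3.5, 3.5, 3.5),
                     effectRadiusVox = 1.6, coupling = 1.2, fwhmMm = 0,
                     effectNoiseSD = 0.02, backgroundNoiseSD = 0.08)
  panel <- genItemPanel(cfg)
  gen <- genVolumes(cfg, panel@meta$truth$slope)
  mi <- longsem:::.buildMeasurementSpec(12, 3, "shared", "shared")
  base <- buildLGCM(mi, growthSpec(), panel = panel)
  mF <- mapVoxelPredictor(panel, gen$volumes, gen$mask, base,
                          mode = "fixed_measurement", seed = 1)
  mR <- mapVoxelPredictor(panel, gen$volumes, gen$mask, base,
                          mode = "full_refit", seed = 1)
  inm <- which(gen$mask & gen$truth)
  expect_true(all(sign(mF@beta[inm]) == sign(mR@beta[inm])))
  strong <- inm[abs(mR@z[inm]) > 4]
  if (length(strong))
    expect_lt(max(abs(mF@z[strong] - mR@z[strong]) / abs(mR@z[strong])), 0.10)
})
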