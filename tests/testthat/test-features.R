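test_that("intensity normalization matches the population-SD definition", {
  v <- ImageVolume(array(c(0, 2, 4, 6, 0, 2, 4, 6), c(2, 2, 2)), 0.8)
  z <- voxelData(normalizeIntensity(v))
  expect_equal(as.vector(z)[1:4],
               c(-1.34164, -0.44721, 0.44721, 1.34164) * c(1, 1, 1, 1),
               tolerance = 1e-4)
  expect_equal(mean(z), 0, tolerance = 1e-6)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-6)

  set.seed(3)
  r <- normalizeIntensity(ImageVolume(array(rnorm(27, 50, 4), c(3, 3, 3))))
  expect_equal(mean(voxelData(r)), 0, tolerance = 1e-6)
  expect_equal(sqrt(mean(voxelData(r)^2)), 1, tolerance = 1e-6)

  expect_error(normalizeIntensity(ImageVolume(array(5, c(3, 3, 3)))),
               "degenerate")
})

test_that("Hessian maps are zero on a flat volume and bounded in [0,1]", {
  z <- hessianShapeFeatures(ImageVolume(array(0, c(16, 16, 16)), 0.8))
  expect_true(all(z@maps == 0))

  set.seed(4)
  v <- ImageVolume(array(rnorm(16^3), c(16, 16, 16)), 0.8)
  fs <- hessianShapeFeatures(v)
  expect_true(all(fs@maps >= 0 & fs@maps <= 1))
  expect_true(all(is.finite(fs@maps)))
  # deterministic: no RNG involved
  expect_identical(fs@maps, hessianShapeFeatures(v)@maps)

  expect_error(hessianShapeFeatures(v, scales_mm = numeric(0)), "config")
})

test_that("blobness peaks at the center of a Gaussian blob", {
  n <- 33; s <- 0.8
  ctr <- (n / 2) * s  # between-voxel center is fine; use voxel 17 center
  ctr <- (17 - 0.5) * s
  x <- (seq_len(n) - 0.5) * s
  blob <- exp(-outer(outer((x - ctr)^2, (x - ctr)^2, "+"), (x - ctr)^2, "+") /
                (2 * 3^2))
  fs <- hessianShapeFeatures(ImageVolume(blob, s))
  bm <- voxelData(featureMap(fs, "blobness"))
  expect_equal(as.vector(which(bm == max(bm), arr.ind = TRUE)[1, ]),
               c(17, 17, 17))
})

test_that("a tube is more vessel-like than blob-like along its axis", {
  n <- 33; s <- 0.8
  x <- (seq_len(n) - 0.5) * s
  ctr <- (17 - 0.5) * s
  cross <- exp(-outer((x - ctr)^2, (x - ctr)^2, "+") / (2 * 1.5^2))
  tube <- array(rep(cross, n), c(n, n, n))  # axis along z
  fs <- hessianShapeFeatures(ImageVolume(aperm(tube, c(3, 1, 2)), s))
  ves <- voxelData(featureMap(fs, "vesselness"))
  blo <- voxelData(featureMap(fs, "blobness"))
  axis_vox <- cbind(5:29, 17, 17)  # on-axis voxels away from the ends
  expect_gt(mean(ves[axis_vox]), mean(blo[axis_vox]))
})

test_that("spheres out-blob equal-radius tubes at structure centers", {
  n <- 33; s <- 0.8
  x <- (seq_len(n) - 0.5) * s
  ctr <- (17 - 0.5) * s
  wins <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    r <- runif(1, 1.5, 3)
    sph <- exp(-outer(outer((x - ctr)^2, (x - ctr)^2, "+"), (x - ctr)^2, "+") /
                 (2 * r^2)) + array(rnorm(n^3, sd = 0.02), c(n, n, n))
    crs <- exp(-outer((x - ctr)^2, (x - ctr)^2, "+") / (2 * r^2))
    tub <- aperm(array(rep(crs, n), c(n, n, n)), c(3, 1, 2)) +
      array(rnorm(n^3, sd = 0.02), c(n, n, n))
    bs <- voxelData(featureMap(hessianShapeFeatures(ImageVolume(sph, s)),
                               "blobness"))[17, 17, 17]
    bt <- voxelData(featureMap(hessianShapeFeatures(ImageVolume(tub, s)),
                               "blobness"))[17, 17, 17]
    if (bs > bt) wins <- wins + 1L
  }
  expect_identical(wins, 10L)
})

test_that("positional features encode coordinates and signed distances", {
  v <- ImageVolume(array(0, c(21, 21, 21)), 0.8)
  fs0 <- positionalFeatures(v)
  expect_identical(featureNames(fs0), c("pos_x", "pos_y", "pos_z"))
  expect_equal(range(fs0@maps), c(0, 1))

  lm <- array(FALSE, c(21, 21, 21)); lm[6, 6, 6] <- TRUE
  fs <- positionalFeatures(v, list(roi = lm))
  d <- voxelData(featureMap(fs, "dist_roi"))
  expect_equal(d[16, 6, 6], 8.0)            # 10 voxels along one axis
  expect_equal(d[6, 6, 6], -0.8)            # inside: negative
  expect_equal(d[9, 10, 6], sqrt(3^2 + 4^2) * 0.8)  # EDT oracle: 3-4-5

  lm2 <- array(FALSE, c(21, 21, 21)); lm2[5:9, 5:9, 5:9] <- TRUE
  fs2 <- positionalFeatures(v, list(block = lm2))
  expect_lt(voxelData(featureMap(fs2, "dist_block"))[7, 7, 7], 0)

  expect_error(positionalFeatures(v, list(bad = array(TRUE, c(5, 5, 5)))),
               "shape")
})

test_that("the assembled stack is finite, named and on the input grid", {
  ph <- testPhantom(5, grid_shape = c(40L, 40L, 40L))
  fs <- buildFeatureStack(ph)
  expect_identical(dim(fs@maps)[1:3], c(40L, 40L, 40L))
  expect_true(all(is.finite(fs@maps)))
  expect_identical(featureNames(fs),
                   c("t1_intensity", "t2star_intensity", "blobness",
                     "vesselness", "sheetness", "pos_x", "pos_y", "pos_z"))
  expect_false(anyDuplicated(featureNames(fs)) > 0)
})
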