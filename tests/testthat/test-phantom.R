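test_that("empty phantom contains only background labels", {
  ph <- generatePhantom(phantomConfig(grid_shape = c(32, 32, 32),
                                      n_nodes = 0, n_vessels = 0,
                                      n_sheets = 0, seed = 1))
  expect_identical(sort(unique(as.vector(voxelData(annotation(ph))))), 0L)
  expect_equal(nrow(nodeProperties(ph)), 0)
})

test_that("a fixed seed reproduces the phantom bit-exactly", {
  cfg <- phantomConfig(grid_shape = c(40, 40, 40), n_nodes = 2,
                       n_vessels = 1, n_sheets = 1, seed = 42)
  a <- generatePhantom(cfg)
  b <- generatePhantom(cfg)
  expect_identical(voxelData(channel(a, "t1")), voxelData(channel(b, "t1")))
  expect_identical(voxelData(channel(a, "t2star")),
                   voxelData(channel(b, "t2star")))
  expect_identical(voxelData(annotation(a)), voxelData(annotation(b)))
  cfg$seed <- 43L
  c_ <- generatePhantom(cfg)
  expect_false(identical(voxelData(channel(a, "t1")),
                         voxelData(channel(c_, "t1"))))
})

test_that("annotation has one connected component per requested node", {
  ph <- generatePhantom(phantomConfig(n_nodes = 5,
                                      node_diameter_range_mm = c(3, 7),
                                      n_vessels = 0, n_sheets = 0,
                                      seed = 7))
  ann <- voxelData(annotation(ph))
  expect_setequal(setdiff(unique(as.vector(ann)), 0L), 1:5)
  expect_identical(oracleComponentCount(ann > 0), 5L)
})

test_that("node properties follow the voxel-center convention", {
  a <- array(0L, c(20, 20, 20))
  a[11, 11, 11] <- 1L  # 0-based index (10,10,10)
  props <- nodeProperties(ImageVolume(a, 0.8))
  expect_equal(c(props$cog_x_mm, props$cog_y_mm, props$cog_z_mm),
               c(8.4, 8.4, 8.4))
  expect_equal(props$volume_ml, 0.8^3 / 1000)

  # 196 voxels at 0.8 mm: volume just above the 0.1 ml training cutoff
  b <- array(0L, c(20, 20, 20))
  b[which(b == 0)[1:196]] <- 1L
  pb <- nodeProperties(ImageVolume(b, 0.8))
  expect_equal(pb$n_voxels, 196)
  expect_equal(pb$volume_ml, 0.100352, tolerance = 1e-12)

  expect_equal(nrow(nodeProperties(ImageVolume(array(0L, c(5, 5, 5)), 0.8))),
               0)
})

test_that("nodes are brighter than background in the T1-like channel", {
  for (seed in c(2, 9, 21)) {
    ph <- testPhantom(seed)
    cfg <- ph@config
    t1 <- voxelData(channel(ph, "t1"))
    inside <- voxelData(annotation(ph)) > 0
    expect_gte(mean(t1[inside]) - mean(t1[!inside]),
               cfg$node_contrast[1] - 3 * cfg$noise_sd)
    expect_equal(length(unique(voxelData(annotation(ph))[inside])),
                 cfg$n_nodes)
  }
})

test_that("impossible geometry raises a placement error", {
  expect_error(
    generatePhantom(phantomConfig(grid_shape = c(16, 16, 16),
                                  n_nodes = 1,
                                  node_diameter_range_mm = c(9, 10),
                                  margin_mm = 6, seed = 1)),
    "placement")
  expect_error(phantomConfig(node_diameter_range_mm = c(3, 12)), "10 mm")
})
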