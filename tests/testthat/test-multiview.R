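test_that("the nine view bases are orthonormal symmetry planes", {
  b <- enumerateViewBases()
  expect_length(b, 9)
  for (x in b) {
    expect_equal(sum(x$u^2), 1, tolerance = 1e-12)
    expect_equal(sum(x$v^2), 1, tolerance = 1e-12)
    expect_equal(sum(x$u * x$v), 0, tolerance = 1e-12)
    expect_equal(x$normal,
                 c(x$u[2] * x$v[3] - x$u[3] * x$v[2],
                   x$u[3] * x$v[1] - x$u[1] * x$v[3],
                   x$u[1] * x$v[2] - x$u[2] * x$v[1]),
                 tolerance = 1e-12)
  }
  # normals pairwise non-parallel
  N <- t(sapply(b, `[[`, "normal"))
  for (i in 1:8) for (j in (i + 1):9)
    expect_lt(abs(sum(N[i, ] * N[j, ])), 1 - 1e-9)
  # each diagonal normal makes 45 degrees with exactly two coordinate axes
  for (i in 4:9) {
    ang <- acos(pmin(1, abs(N[i, ]))) * 180 / pi
    expect_identical(sum(abs(ang - 45) < 1e-9), 2L)
    expect_identical(sum(abs(ang - 90) < 1e-9), 1L)
  }
  # views 0-2 are the axis-aligned planes
  for (i in 1:3) expect_setequal(abs(c(b[[i]]$u, b[[i]]$v, b[[i]]$normal)),
                                 c(0, 0, 0, 0, 0, 0, 1, 1, 1))
})

test_that("patch center reproduces the interpolated volume value", {
  set.seed(10)
  vol <- ImageVolume(array(rnorm(30^3), c(30, 30, 30)), 0.8)
  b <- enumerateViewBases()
  ctr <- c((15 - 0.5) * 0.8, (16 - 0.5) * 0.8, (17 - 0.5) * 0.8)
  for (i in c(1, 4, 8)) {
    p <- extractPatch(vol, ctr, b[[i]], size = 9)
    expect_equal(p[5, 5], voxelData(vol)[15, 16, 17], tolerance = 1e-12)
  }
  # off-voxel center: trilinear mean of the two bracketing voxels
  ctr2 <- ctr + c(0.4, 0, 0)
  p2 <- extractPatch(vol, ctr2, b[[1]], size = 9)
  expect_equal(p2[5, 5],
               mean(voxelData(vol)[15:16, 16, 17]), tolerance = 1e-12)
  expect_error(extractPatch(vol, ctr, b[[1]], size = 8), "odd")
})

test_that("axis-aligned extraction equals array slicing on voxel centers", {
  set.seed(11)
  n <- 80
  vol <- ImageVolume(array(rnorm(n^3), c(n, n, n)), 0.8)
  ctr_idx <- c(40, 41, 39)
  ctr <- (ctr_idx - 0.5) * 0.8
  b <- enumerateViewBases()
  p0 <- extractPatch(vol, ctr, b[[1]], size = 65)
  want0 <- voxelData(vol)[ctr_idx[1] + (-32:32), ctr_idx[2] + (-32:32),
                          ctr_idx[3]]
  expect_equal(p0, want0, tolerance = 1e-9, ignore_attr = TRUE)
  p1 <- extractPatch(vol, ctr, b[[2]], size = 65)  # u = y, v = z
  want1 <- voxelData(vol)[ctr_idx[1], ctr_idx[2] + (-32:32),
                          ctr_idx[3] + (-32:32)]
  expect_equal(p1, want1, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("constant volumes yield constant patches with zero padding", {
  vol <- ImageVolume(array(3, c(30, 30, 30)), 0.8)
  ctr <- c(12, 12, 12)
  p <- extractPatch(vol, ctr, enumerateViewBases()[[1]], size = 65)
  # interior samples keep the constant; samples beyond the volume are 0
  expect_equal(p[33, 33], 3, tolerance = 1e-12)
  expect_equal(p[1, 1], 0)   # far corner lies outside the 24 mm volume
  expect_true(all(p >= -1e-9 & p <= 3 + 1e-9))  # fade only at the border
})

test_that("view subsets are consistent (1 within 3 within 9)", {
  set.seed(12)
  vol <- ImageVolume(array(rnorm(40^3), c(40, 40, 40)), 0.8)
  ctr <- c(16, 16, 16)
  v1 <- makeViewSet(vol, ctr, 1L, size = 33)
  v3 <- makeViewSet(vol, ctr, 3L, size = 33)
  v9 <- makeViewSet(vol, ctr, 9L, size = 33)
  expect_identical(v1$view_ids, 0L)
  expect_identical(v3$view_ids, 0:2)
  expect_identical(v9$view_ids, 0:8)
  expect_identical(v1$patches[, , 1], v9$patches[, , 1])
  expect_identical(v3$patches, v9$patches[, , 1:3])
  expect_error(makeViewSet(vol, ctr, 5L), "config")
})

test_that("axis permutation of the volume permutes axis-aligned patches", {
  set.seed(13)
  n <- 40
  a <- array(rnorm(n^3), c(n, n, n))
  vol <- ImageVolume(a, 0.8)
  volp <- ImageVolume(aperm(a, c(2, 3, 1)), 0.8)  # x<-y, y<-z, z<-x
  ctr_idx <- c(18, 20, 22)
  ctr <- (ctr_idx - 0.5) * 0.8
  ctrp <- (c(20, 22, 18) - 0.5) * 0.8
  b <- enumerateViewBases()
  # view 1 of the original (u=y, v=z) equals view 0 (u=x, v=y) of the
  # cyclically permuted volume at the permuted center
  p_orig <- extractPatch(vol, ctr, b[[2]], size = 21)
  p_perm <- extractPatch(volp, ctrp, b[[1]], size = 21)
  expect_equal(p_orig, p_perm, tolerance = 1e-12)
})

test_that("oblique patches of a centered ball are rotation-invariant", {
  n <- 41; s <- 0.8
  x <- (seq_len(n) - 0.5) * s
  ctr <- (21 - 0.5) * s
  ball <- exp(-outer(outer((x - ctr)^2, (x - ctr)^2, "+"), (x - ctr)^2, "+") /
                (2 * 4^2))
  vol <- ImageVolume(ball, s)
  ps <- makeViewSet(vol, rep(ctr, 3), 9L, size = 33)$patches
  ref <- ps[, , 1]
  # trilinear interpolation on a 0.8 mm grid leaves O(h^2) residuals
  for (v in 2:9)
    expect_lt(max(abs(ps[, , v] - ref)), 2e-2)
})
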