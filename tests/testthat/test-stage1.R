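# helper: a FeatureStack with given maps on a grid
fakeStack <- function(maps, spacing = 0.8) {
  dims <- dim(maps[[1]])
  arr <- array(unlist(maps, use.names = FALSE), c(dims, length(maps)))
  new("FeatureStack", maps = arr, featureNames = names(maps),
      spacing = spacing, scales = numeric(0))
}

test_that("voxel training rules: volume cutoff, COG radius, balance", {
  dims <- c(40, 40, 40); s <- 0.8
  a <- array(0L, dims)
  # node 1: 147 voxels (~0.075 ml) -> below the cutoff, excluded
  cx <- 8; a[cx + (-3:3), cx + (-3:3), cx + (-1:1)] <- 1L
  a[30 + (-4:4), 30 + (-4:4), 30 + (-2:2)] <- 2L           # 405 voxels block
  ann <- ImageVolume(a, s)
  props <- nodeProperties(ann)
  expect_lt(props$volume_ml[props$label == 1], 0.1)
  expect_gte(props$volume_ml[props$label == 2], 0.1)

  set.seed(1)
  fs <- fakeStack(list(f1 = array(rnorm(prod(dims)), dims),
                       f2 = array(rnorm(prod(dims)), dims)), s)
  ts <- buildVoxelTrainingSet(fs, ann, n_per_class = 500, seed = 3)
  expect_identical(sum(ts$y == 1), sum(ts$y == -1))
  pos_vox <- ts$voxel[ts$y == 1]
  expect_true(all(a[pos_vox] == 2L))  # the sub-0.1 ml node contributes none
  ai2 <- arrayInd(pos_vox, dims)
  ctr <- unlist(props[props$label == 2, c("cog_x_mm", "cog_y_mm", "cog_z_mm")])
  d <- sqrt(((ai2[, 1] - 0.5) * s - ctr[1])^2 +
            ((ai2[, 2] - 0.5) * s - ctr[2])^2 +
            ((ai2[, 3] - 0.5) * s - ctr[3])^2)
  expect_true(all(d <= 4))
  # deterministic per seed
  ts2 <- buildVoxelTrainingSet(fs, ann, n_per_class = 500, seed = 3)
  expect_identical(ts$voxel, ts2$voxel)

  # only sub-threshold nodes -> empty positive class
  a2 <- array(0L, dims); a2[5:8, 5:8, 5:8] <- 1L  # 64 voxels, 0.033 ml
  expect_error(buildVoxelTrainingSet(fs, ImageVolume(a2, s)), "empty-class")
})

test_that("one boosting round equals exhaustive stump search", {
  for (seed in c(1, 5, 12)) {
    set.seed(seed)
    X <- matrix(rnorm(60 * 4), 60, 4)
    y <- sample(c(-1, 1), 60, replace = TRUE)
    m <- fitGentleBoost(X, y, n_rounds = 1)
    o <- oracleBestStump(X, y, rep(1 / 60, 60))
    st <- stumps(m)
    expect_equal(st$feature_index, o$feature)
    expect_equal(st$threshold, o$threshold)
    expect_equal(st$response_ge, o$response_ge, tolerance = 1e-12)
    expect_equal(st$response_lt, o$response_lt, tolerance = 1e-12)
  }
})

test_that("boosting separates a separable toy set and is weight-invariant", {
  set.seed(2)
  X <- rbind(matrix(rnorm(80, mean = 2, sd = 0.5), 40, 2),
             matrix(rnorm(80, mean = -2, sd = 0.5), 40, 2))
  y <- rep(c(1, -1), each = 40)
  m <- fitGentleBoost(X, y, n_rounds = 50)
  F <- boostScore(m, X)
  expect_identical(mean(sign(F) != y), 0)  # zero training error

  # duplicating every row leaves the fitted model unchanged
  m2 <- fitGentleBoost(rbind(X, X), c(y, y), n_rounds = 50)
  expect_equal(stumps(m), stumps(m2))

  expect_error(fitGentleBoost(X, rep(1, 80)), "class")
  expect_error(fitGentleBoost(X, rep(0.5, 80)), "-1")
})

test_that("weighted exponential loss decreases over boosting rounds", {
  for (seed in c(3, 8)) {
    set.seed(seed)
    X <- matrix(rnorm(100 * 3), 100, 3)
    y <- ifelse(X[, 1] + 0.5 * X[, 2] + rnorm(100, sd = 0.8) > 0, 1, -1)
    losses <- errs <- numeric(0)
    for (r in c(1, 5, 15, 40)) {
      m <- fitGentleBoost(X, y, n_rounds = r)
      F <- boostScore(m, X)
      losses <- c(losses, mean(exp(-y * F)))
      errs <- c(errs, mean(sign(F) != y))
    }
    expect_true(all(diff(losses) <= 1e-10))
    expect_lte(tail(errs, 1), errs[1])
  }
})

test_that("likelihood is the logistic of twice the additive score", {
  dims <- c(8, 8, 8)
  fs <- fakeStack(list(f1 = array(seq_len(512) / 512, dims)), 0.8)
  empty <- new("BoostModel",
               stumps = data.frame(feature_index = integer(0),
                                   threshold = numeric(0),
                                   response_ge = numeric(0),
                                   response_lt = numeric(0)),
               featureNames = "f1", nRounds = 0L)
  L0 <- predictLikelihood(empty, fs)
  expect_true(all(voxelData(L0) == 0.5))

  one <- new("BoostModel",
             stumps = data.frame(feature_index = 1L, threshold = 0.5,
                                 response_ge = 0.8, response_lt = -0.8),
             featureNames = "f1", nRounds = 1L)
  L1 <- voxelData(predictLikelihood(one, fs))
  expect_true(all(L1 >= 0 & L1 <= 1))
  expect_equal(unique(round(as.vector(L1), 10)),
               round(1 / (1 + exp(-2 * c(-0.8, 0.8))), 10))

  expect_error(predictLikelihood(one, fakeStack(list(g = array(0, dims)))),
               "mismatch")
})

test_that("positive likelihood grows monotonically with rounds on positives", {
  set.seed(6)
  X <- rbind(matrix(rnorm(60, 1.5, 0.4), 30, 2),
             matrix(rnorm(60, -1.5, 0.4), 30, 2))
  y <- rep(c(1, -1), each = 30)
  mean_pos <- sapply(c(1, 3, 10, 30), function(r) {
    F <- boostScore(fitGentleBoost(X, y, r), X)
    mean(1 / (1 + exp(-2 * F[y == 1])))
  })
  expect_true(all(diff(mean_pos) >= -1e-12))
  expect_gt(tail(mean_pos, 1), 0.99)
})

test_that("candidate detection handles peaks and plateaus", {
  dims <- c(24, 24, 24); s <- 0.8
  x <- (seq_len(24) - 0.5) * s
  ctr <- (12 - 0.5) * s
  L <- exp(-outer(outer((x - ctr)^2, (x - ctr)^2, "+"), (x - ctr)^2, "+") / 8)
  cand <- detectCandidates(ImageVolume(L, s))
  expect_identical(nrow(cand), 1L)
  expect_equal(unlist(cand[1, 1:3], use.names = FALSE), c(12, 12, 12))

  # 3 x 3 x 1 plateau of the maximal value -> single central candidate
  P <- array(0, dims)  # background below the floor
  P[11:13, 11:13, 12] <- 0.9
  cp <- detectCandidates(ImageVolume(P, s))
  expect_identical(nrow(cp), 1L)
  expect_equal(unlist(cp[1, 1:3], use.names = FALSE), c(12, 12, 12))
  expect_equal(cp$likelihood, 0.9)

  # two equal peaks 20 mm apart (25 voxels) are both kept
  Q <- array(0, c(32, 24, 24))
  Q[4, 12, 12] <- 0.8
  Q[29, 12, 12] <- 0.8
  cq <- detectCandidates(ImageVolume(Q, s))
  expect_identical(nrow(cq), 2L)

  expect_error(detectCandidates(ImageVolume(array(2, dims), s)), "0, 1|\\[0")
})

test_that("candidate detection equals the brute-force windowed oracle", {
  dims <- c(20, 20, 20); s <- 0.8
  for (seed in 1:4) {
    set.seed(seed)
    base <- array(0, dims)
    for (k in 1:3) {
      c0 <- runif(3, 4, 12)
      x <- (seq_len(20) - 0.5) * s
      base <- base + runif(1, 0.3, 1) *
        exp(-outer(outer((x - c0[1] * s)^2, (x - c0[2] * s)^2, "+"),
                   (x - c0[3] * s)^2, "+") / runif(1, 2, 10))
    }
    base <- base / max(base)
    base <- round(base, 2)  # induce ties and plateaus
    got <- detectCandidates(ImageVolume(base, s))
    want <- oracleDetectCandidates(base, s)
    expect_identical(got[c("index_x", "index_y", "index_z", "likelihood")],
                     want, info = paste("seed", seed))
  }
})

test_that("stage 1 finds nearly all nodes of 4 mm and larger", {
  cfg <- phantomStudyConfig(1)
  train_ph <- lapply(1:2, function(i) testPhantom(100 + i))
  model <- nodecad:::.trainStage1(train_ph, cfg, 55L)
  found <- 0L; total <- 0L
  for (seed in 201:204) {
    ph <- testPhantom(seed)
    det <- nodecad:::.detectOnPhantom(ph, model, cfg)
    big <- ph@nodeTable$label[ph@nodeTable$diameter_mm >= 4]
    total <- total + length(big)
    found <- found + sum(big %in% det$candidates$node_label)
  }
  expect_gte(found / total, 0.9)
})
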