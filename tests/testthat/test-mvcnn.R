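test_that("forward-pass shapes match the reference architecture table", {
  m <- buildNetwork(networkSpec(3), seed = 1)
  set.seed(1)
  out <- scoreCandidates(m, array(rnorm(65 * 65 * 3), c(65, 65, 3, 1)),
                         trace = TRUE)
  tr <- out$trace
  expect_identical(tr$input, c(65L, 65L, 1L))
  expect_identical(tr$conv1, c(61L, 61L, 24L))
  expect_identical(tr$pool1, c(30L, 30L, 24L))
  expect_identical(tr$conv2, c(26L, 26L, 48L))
  expect_identical(tr$pool2, c(13L, 13L, 48L))
  expect_identical(tr$conv3, c(9L, 9L, 96L))
  expect_identical(tr$concat[3], 3L * 9L * 9L * 96L)
  expect_identical(tr$fc1[3], 512L)
  expect_identical(tr$fc2[3], 2L)
  # analytic trace agrees with the executed forward pass
  at <- networkShapeTrace(networkSpec(3))
  expect_identical(at$width[2:6], c(61L, 30L, 26L, 13L, 9L))
  expect_identical(at$channels[2:6], c(24L, 24L, 48L, 48L, 96L))
})

test_that("view branches are independent (no weight sharing)", {
  m3 <- buildNetwork(networkSpec(3), seed = 2)
  expect_gt(parameterCount(m3), parameterCount(buildNetwork(networkSpec(1),
                                                            seed = 2)))
  # branch weights are distinct objects, not copies of each other
  expect_false(identical(m3@weights$views[[1]]$W1, m3@weights$views[[2]]$W1))
  # with zero input into view 1 (and zero biases), perturbing view-1 weights
  # cannot change the output: the other branches are untouched
  set.seed(3)
  p <- array(rnorm(65 * 65 * 3 * 2), c(65, 65, 3, 2))
  p[, , 1, ] <- 0
  s_before <- scoreCandidates(m3, p)
  m3b <- m3
  m3b@weights$views[[1]]$W1 <- m3b@weights$views[[1]]$W1 * 2
  m3b@weights$views[[1]]$W3 <- m3b@weights$views[[1]]$W3 * -1
  expect_equal(scoreCandidates(m3b, p), s_before, tolerance = 1e-7)
  # perturbing view-2 weights with signal in view 2 does change it
  m3c <- m3
  m3c@weights$views[[2]]$W1 <- m3c@weights$views[[2]]$W1 * 2
  expect_false(isTRUE(all.equal(scoreCandidates(m3c, p), s_before,
                                tolerance = 1e-7)))
})

test_that("analytic gradients match finite differences", {
  spec <- networkSpec(n_views = 3, input_size = 33,
                      conv_channels = c(2L, 3L, 4L), fc_units = 8L)
  m <- buildNetwork(spec, seed = 4)
  set.seed(5)
  p <- array(rnorm(33 * 33 * 3 * 4), c(33, 33, 3, 4))
  y <- c(0L, 1L, 1L, 0L)
  res <- nodecad:::.cnnLossGrads(m@weights, p, y, 5e-4)
  g <- unlist(res$grads, use.names = FALSE)
  w0 <- unlist(m@weights, use.names = FALSE)
  set.seed(6)
  for (trial in 1:3) {
    d <- rnorm(length(g)); d <- d / sqrt(sum(d^2))
    eps <- 2e-3
    lp <- nodecad:::.cnnLossGrads(relist(w0 + eps * d, m@weights), p, y,
                                  5e-4)$loss
    lm <- nodecad:::.cnnLossGrads(relist(w0 - eps * d, m@weights), p, y,
                                  5e-4)$loss
    expect_equal((lp - lm) / (2 * eps), sum(g * d), tolerance = 5e-3)
  }
})

test_that("one small SGD step decreases the loss on a fixed batch", {
  spec <- networkSpec(n_views = 3, input_size = 33,
                      conv_channels = c(2L, 3L, 4L), fc_units = 8L)
  ok <- 0L
  for (seed in 1:5) {
    m <- buildNetwork(spec, seed = seed)
    task <- makePatchTask(8, 3, size = 33, seed = seed + 50)
    res <- nodecad:::.cnnLossGrads(m@weights, task$patches, task$labels, 5e-4)
    w1 <- relist(unlist(m@weights, use.names = FALSE) -
                   1e-4 * unlist(res$grads, use.names = FALSE), m@weights)
    l1 <- nodecad:::.cnnLossGrads(w1, task$patches, task$labels, 5e-4)$loss
    if (l1 < res$loss) ok <- ok + 1L
  }
  expect_gte(ok, 5L)
})

test_that("minibatches are class-balanced and training learns the task", {
  task_tr <- makePatchTask(25, 1, seed = 21)
  task_va <- makePatchTask(10, 1, seed = 22)
  m <- buildNetwork(networkSpec(1), seed = 7)
  cfg <- trainConfig(learning_rate = 1e-3, minibatches_per_epoch = 8,
                     max_epochs = 4, early_stop_patience_epochs = 20,
                     seed = 8)
  fit <- trainNetwork(m, task_tr$patches, task_tr$labels, task_va$patches,
                      task_va$labels, cfg, log_batch_classes = TRUE)
  expect_true(all(fit$batch_pos_counts == 16L))
  expect_gte(fit$best_val_accuracy, 0.95)
  expect_identical(names(fit$history),
                   c("epoch", "train_loss", "val_accuracy"))
  # deterministic: same seed, same history
  fit2 <- trainNetwork(m, task_tr$patches, task_tr$labels, task_va$patches,
                       task_va$labels, cfg)
  expect_equal(fit$history, fit2$history)
})

test_that("signal-free input plateaus at chance and stops early", {
  spec <- networkSpec(n_views = 1, input_size = 33,
                      conv_channels = c(2L, 3L, 4L), fc_units = 8L)
  m <- buildNetwork(spec, seed = 9)
  z_tr <- array(0, c(33, 33, 1, 20))
  z_va <- array(0, c(33, 33, 1, 10))
  l_tr <- rep(c(0L, 1L), 10)
  l_va <- rep(c(0L, 1L), 5)
  cfg <- trainConfig(minibatches_per_epoch = 2, max_epochs = 30,
                     early_stop_patience_epochs = 3, seed = 10)
  fit <- trainNetwork(m, z_tr, l_tr, z_va, l_va, cfg)
  expect_equal(fit$best_val_accuracy, 0.5, tolerance = 1e-9)
  expect_lte(nrow(fit$history), fit$best_epoch + 3 + 1)
})

test_that("scores are probabilities, deterministic and order-invariant", {
  spec <- networkSpec(n_views = 3, input_size = 33,
                      conv_channels = c(4L, 6L, 8L), fc_units = 16L)
  m <- buildNetwork(spec, seed = 11)
  set.seed(12)
  p <- array(rnorm(33 * 33 * 3 * 7), c(33, 33, 3, 7))
  s <- scoreCandidates(m, p)
  expect_true(all(s >= 0 & s <= 1))
  raw <- nodecad:::.cnnPredict(m@weights, p)$probs
  expect_equal(rowSums(raw), rep(1, 7), tolerance = 1e-6)
  # duplicated patch set scores identically
  pp <- p[, , , c(1, 1, 2:7), drop = FALSE]
  s2 <- scoreCandidates(m, pp)
  expect_equal(s2[1], s2[2], tolerance = 0)
  # batch order invariance
  perm <- c(4, 1, 7, 3, 2, 6, 5)
  expect_equal(scoreCandidates(m, p[, , , perm, drop = FALSE]), s[perm],
               tolerance = 1e-6)
  expect_error(scoreCandidates(m, array(0, c(33, 33, 9, 2))), "view")
})

test_that("CNN training set includes missed nodes and subsampled FPs", {
  dims <- c(30, 30, 30); s <- 0.8
  a <- array(0L, dims)
  a[8:12, 8:12, 8:12] <- 1L
  a[20:24, 20:24, 20:24] <- 2L
  ann <- ImageVolume(a, s)
  # stage-1 candidates: one inside node 1, none in node 2, three FPs
  cand <- data.frame(index_x = c(10, 3, 15, 27), index_y = c(10, 3, 15, 27),
                     index_z = c(10, 3, 15, 27))
  cand$pos_mm_x <- (cand$index_x - 0.5) * s
  cand$pos_mm_y <- (cand$index_y - 0.5) * s
  cand$pos_mm_z <- (cand$index_z - 0.5) * s
  cand$likelihood <- c(0.9, 0.5, 0.4, 0.3)
  cand <- matchCandidates(cand, ann)
  ts <- buildCnnTrainingSet(cand, ann, fp_subsample = 1.0, seed = 1)
  expect_identical(sum(ts$source == "tp"), 1L)
  expect_identical(sum(ts$source == "fn"), 1L)  # node 2 kept via its COG
  expect_identical(sum(ts$source == "fp"), 3L)
  props <- nodeProperties(ann)
  fn <- ts[ts$source == "fn", ]
  expect_equal(fn$pos_mm_x, props$cog_x_mm[props$label == 2])
  # fractional and counted subsampling, reproducible per seed
  ts2 <- buildCnnTrainingSet(cand, ann, fp_subsample = 2 / 3, seed = 5)
  expect_identical(sum(ts2$source == "fp"), 2L)
  ts3 <- buildCnnTrainingSet(cand, ann, fp_subsample = 2 / 3, seed = 5)
  expect_identical(ts2$candidate_row, ts3$candidate_row)
  expect_error(buildCnnTrainingSet(cand[2:3, ],
                                   ImageVolume(array(0L, dims), s)),
               "positives")
})
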