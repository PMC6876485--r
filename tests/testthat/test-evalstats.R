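test_that("candidate matching follows the FROC hit convention", {
  dims <- c(20, 20, 20); s <- 0.8
  a <- array(0L, dims)
  a[5:9, 5:9, 5:9] <- 1L
  ann <- ImageVolume(a, s)
  cand <- data.frame(index_x = c(7, 15, 6), index_y = c(7, 15, 6),
                     index_z = c(7, 15, 6),
                     likelihood = c(0.9, 0.7, 0.4))
  m <- matchCandidates(cand, ann)
  expect_identical(m$node_label, c(1L, NA, 1L))
  expect_error(matchCandidates(data.frame(index_x = 25, index_y = 1,
                                          index_z = 1, likelihood = 1), ann),
               "grid")

  # two candidates in one node (0.9 / 0.4): node detected for t <= 0.9,
  # the extra candidate is ignored, FP count unchanged
  cur <- frocCurve(m, n_nodes = 1, n_images = 1)
  op <- operatingPoints(cur)
  expect_equal(op$sensitivity[op$threshold == 0.9], 1)
  expect_equal(op$fp_per_image[op$threshold == 0.9], 0)
  # the ignored 0.4 candidate adds neither an operating point nor an FP
  expect_identical(op$threshold, c(0.9, 0.7))
  expect_equal(max(op$fp_per_image), 1)  # only the 0.7 FP ever counts
})

test_that("FROC operating points match the hand-enumerated example", {
  # 2 nodes, 1 detected at 0.8; FPs at 0.9, 0.7, 0.6; 1 image
  img <- list(scores = c(0.8, 0.9, 0.7, 0.6),
              node_label = c(1L, NA, NA, NA), n_nodes = 2L)
  cur <- frocCurve(list(img))
  f <- nodecad:::.frocInterp(cur)
  op <- operatingPoints(cur)
  # between thresholds .8 and .7 (e.g. t = .75): sens .5, 1 FP/image
  expect_equal(op$sensitivity[op$threshold == 0.8], 0.5)
  expect_equal(op$fp_per_image[op$threshold == 0.8], 1)
  # at t = .5 every FP counts
  expect_equal(op$sensitivity[op$threshold == 0.6], 0.5)
  expect_equal(op$fp_per_image[op$threshold == 0.6], 3)
  expect_true(all(diff(op$sensitivity) >= 0))  # monotone as t drops

  # perfect detector reaches sensitivity 1 at 0 FP
  perf <- frocCurve(list(list(scores = c(0.9, 0.8), node_label = c(1L, 2L),
                              n_nodes = 2L)))
  expect_equal(max(perf@sensitivity), 1)
  expect_equal(perf@fpPerImage[perf@sensitivity == 1][1], 0)
  expect_error(frocCurve(list(list(scores = 1, node_label = NA,
                                   n_nodes = 0L))), "node")
})

test_that("partial AUC integrates the curve as specified", {
  mk <- function(fp, sens) new("FROCCurve", thresholds = seq_along(fp),
                               sensitivity = sens, fpPerNode = fp,
                               fpPerImage = fp, nNodes = 1L, nImages = 1L)
  # perfect detector: sensitivity 1 throughout -> the full band area
  expect_equal(partialAUC(mk(c(0.1, 40), c(1, 1))), 31.75)
  # constant 0.5
  expect_equal(partialAUC(mk(c(0.1, 40), c(0.5, 0.5))), 15.875)
  # piecewise curve, hand integration:
  # (16-0.25)*(0.6+0.8)/2 + (32-16)*(0.8+0.9)/2 = 11.025 + 13.6
  pw <- mk(c(0.25, 16, 32), c(0.6, 0.8, 0.9))
  expect_equal(partialAUC(pw), 24.625)
  expect_equal(partialAUC(pw), oraclePAUC(pw@fpPerNode, pw@sensitivity,
                                          0.25, 32), tolerance = 1e-6)
  expect_error(partialAUC(pw, 5, 5), "config")
})

test_that("FROC and pAUC equal brute-force recounts on small instances", {
  for (seed in 1:5) {
    set.seed(seed)
    n_img <- 3
    imgs <- lapply(seq_len(n_img), function(i) {
      n_nodes <- sample(1:4, 1)
      n_hit <- sample(0:n_nodes, 1)
      n_fp <- sample(0:10, 1)
      scores <- round(runif(n_hit + n_fp), 2)  # duplicates likely
      list(scores = scores,
           node_label = c(seq_len(n_hit),
                          rep(NA_integer_, n_fp))[sample.int(n_hit + n_fp)],
           n_nodes = n_nodes)
    })
    # keep instances small (<= 50 candidates in total)
    stopifnot(sum(lengths(lapply(imgs, `[[`, "scores"))) <= 50)
    cur <- frocCurve(imgs)
    pooled <- nodecad:::.poolDetections(imgs)
    want <- oracleFROC(pooled$node_scores, pooled$fp_scores,
                       pooled$n_nodes, n_img)
    got <- operatingPoints(cur)
    expect_equal(got, want, tolerance = 1e-12)
    expect_equal(partialAUC(cur, 0.25, 8),
                 oraclePAUC(cur@fpPerNode, cur@sensitivity, 0.25, 8),
                 tolerance = 1e-5)
  }
})

test_that("bootstrap bands behave like percentile bands", {
  one <- list(scores = c(0.9, 0.8, 0.6, 0.5, 0.3),
              node_label = c(1L, 2L, NA, NA, NA), n_nodes = 3L)
  same <- lapply(1:6, function(i) one)
  bt <- bootstrapFROC(list(s = same), n_boot = 50, seed = 3)
  # identical patients -> every resample gives the same curve
  expect_true(all(bt$bands$s$ci_hi - bt$bands$s$ci_lo == 0))
  expect_equal(unname(unlist(bt$pauc[c("ci_lo", "ci_hi")])),
               rep(bt$pauc$pauc, 2))

  set.seed(4)
  varied <- lapply(1:20, function(i) {
    n_fp <- sample(2:6, 1)
    list(scores = c(runif(2, 0.5, 1), runif(n_fp, 0, 0.8)),
         node_label = c(1L, 2L, rep(NA_integer_, n_fp)), n_nodes = 2L)
  })
  bt2 <- bootstrapFROC(list(s = varied), n_boot = 400, seed = 5)
  b <- bt2$bands$s
  expect_true(all(b$ci_lo - 1e-12 <= b$sensitivity &
                  b$sensitivity <= b$ci_hi + 1e-12))
  # replicate pAUC distribution centered near the point estimate
  se <- sd(bt2$pauc_reps[, 1])
  expect_lt(abs(mean(bt2$pauc_reps[, 1]) - bt2$pauc$pauc), 2 * se)
  # deterministic per seed
  bt3 <- bootstrapFROC(list(s = varied), n_boot = 400, seed = 5)
  expect_identical(bt2$pauc_reps, bt3$pauc_reps)
  expect_error(bootstrapFROC(list(s = varied[1]), n_boot = 10), "degenerate")
})

test_that("the one-sided bootstrap test is calibrated under the null", {
  set.seed(6)
  pvals <- replicate(40, {
    patients <- lapply(1:10, function(i) {
      n_fp <- sample(3:8, 1)
      mk <- function() list(scores = c(runif(2, 0.4, 1), runif(n_fp, 0, 0.9)),
                            node_label = c(1L, 2L, rep(NA_integer_, n_fp)),
                            n_nodes = 2L)
      list(A = mk(), B = mk())  # same generative law, independent draws
    })
    bt <- bootstrapFROC(list(A = lapply(patients, `[[`, "A"),
                             B = lapply(patients, `[[`, "B")),
                        n_boot = 200, fp_range = c(0.25, 8),
                        seed = sample.int(1e6, 1))
    compareSystems(bt$pauc_reps[, "A"], bt$pauc_reps[, "B"])$p_raw
  })
  expect_equal(mean(pvals), 0.5, tolerance = 0.1)

  # Bonferroni mapping is exact and capped
  expect_equal(compareSystems(c(1, 2, 3), c(2, 3, 4))$p_raw, 1 / 4)
  fake <- compareSystems(rep(0, 99), rep(1, 99), n_comparisons = 6)
  expect_equal(fake$p_raw, 0.01)
  expect_equal(fake$p_adjusted, 0.06)
  capped <- compareSystems(c(rep(0, 50), rep(2, 49)), rep(1, 99),
                           n_comparisons = 6)
  expect_equal(capped$p_raw, 0.5)
  expect_equal(capped$p_adjusted, 1)
  expect_error(compareSystems(1:3, 1:4), "unpaired")
})

test_that("patient folds are balanced, disjoint and complete", {
  counts <- setNames(rep(2L, 10), paste0("p", 1:10))
  f <- stratifiedPatientFolds(counts, k = 5, seed = 1)
  expect_identical(sort(unique(f$fold)), 1:5)
  expect_true(all(f$fold_node_counts == 4))
  expect_identical(sort(names(f$fold)), sort(names(counts)))

  for (seed in 1:5) {
    set.seed(seed)
    counts2 <- setNames(sample(0:9, 13, replace = TRUE), paste0("q", 1:13))
    f2 <- stratifiedPatientFolds(counts2, k = 5, seed = seed)
    expect_identical(length(f2$fold), 13L)
    expect_lte(max(f2$fold_node_counts) - min(f2$fold_node_counts),
               max(counts2))
    # fold roles: each run tests one fold, validates another
    expect_identical(f2$schedule$test_fold, 1:5)
    expect_true(all(f2$schedule$test_fold != f2$schedule$val_fold))
  }
  expect_error(stratifiedPatientFolds(c(a = 1, b = 2), k = 5), "fewer")
})

test_that("external FROC tables are parsed across delimiters", {
  d <- withr::local_tempdir()
  pts <- data.frame(fp = c(0.5, 2, 8, 24), sens = c(40, 60, 75, 90))
  f1 <- file.path(d, "comma.csv")
  writeLines(c("fp_per_node,sensitivity",
               paste(pts$fp, pts$sens, sep = ",")), f1)
  f2 <- file.path(d, "tab.tsv")
  writeLines(paste(pts$fp, pts$sens / 100, sep = "\t"), f2)
  t1 <- readFROCTable(f1)
  t2 <- readFROCTable(f2)
  expect_equal(t1$sensitivity, c(0.4, 0.6, 0.75, 0.9))  # percent rescaled
  expect_equal(t1$fp, t2$fp)
  expect_equal(t1$sensitivity, t2$sensitivity)
  cur <- frocFromTable(t1)
  expect_equal(fpAtSensitivity(cur, 0.6, per = "node"), 2)
  # linear interpolation between (2, .6) and (8, .75): 0.7 at fp = 6
  expect_equal(fpAtSensitivity(cur, 0.7, per = "node"), 6)
  expect_equal(partialAUC(cur, 0.5, 24),
               oraclePAUC(cur@fpPerNode, cur@sensitivity, 0.5, 24),
               tolerance = 1e-6)
})
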