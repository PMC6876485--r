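# End-to-end orchestration: dataset simulation, stage-1 detection, CNN
# false-positive reduction with patient-level cross-validation, and FROC
# evaluation. The run* functions operate on directories (used by the CLI);
# runComparisonExperiment() performs the whole comparison in memory.

#' Default pipeline configuration
#'
#' Aggregates the reference defaults of every stage: 200 boosting rounds,
#' the 10 mm spherical candidate window, 65 x 65 patches, the standard
#' network and training protocol, and the 0.25-32 FP/node partial-AUC
#' range. The global \code{seed} fans out to per-stage seeds by fixed
#' offsets so that a single seed reproduces a full run.
#'
#' @return nested configuration list.
#' @export
pipelineConfig <- function() {
  list(
    phantom = phantomConfig(),
    simulate = list(n_phantoms = 20L, n_train = 4L),
    features = list(scales_mm = c(1.6, 2.4, 3.2), hessian_channel = "t1"),
    stage1 = list(n_rounds = 200L, n_per_class = 2000L,
                  min_volume_ml = 0.1, cog_radius_mm = 4,
                  window_diameter_mm = 10, floor = 0.01),
    multiview = list(size = 65L, n_views = 3L),
    cnn = trainConfig(),
    cnn_fp_subsample = 1.0,
    eval = list(fp_range = c(0.25, 32), n_boot = 1000L,
                sensitivity_target = 0.8),
    seed = 1L)
}

#' Desk-scale phantom study configuration
#'
#' The configuration used for the package's reference phantom experiment:
#' 20 evaluation phantoms plus 4 stage-1 training phantoms at the default
#' 64^3 / 0.8 mm geometry, the full stage-1 protocol (200 boosting rounds,
#' 10 mm window), the 3-view network, and a shortened CNN training schedule
#' (learning rate 1e-3, 10 minibatches per epoch, 5 epochs). With tens of
#' phantoms the discrimination task is far easier than clinical MRL, so a
#' few hundred balanced minibatches saturate validation accuracy; the
#' larger step size compensates for the proportionally fewer updates. All
#' other settings keep the reference defaults.
#'
#' @param seed global seed for the run.
#' @return a \code{\link{pipelineConfig}} list.
#' @export
phantomStudyConfig <- function(seed = 1L) {
  cfg <- pipelineConfig()
  cfg$cnn <- trainConfig(learning_rate = 1e-3, minibatches_per_epoch = 10L,
                         max_epochs = 5L, early_stop_patience_epochs = 20L)
  cfg$seed <- as.integer(seed)
  cfg
}

# derived per-stage seeds (fixed offsets from the global seed)
.fanSeeds <- function(seed) {
  base <- (as.integer(seed) %% 10000L) * 100000L
  list(phantom_train = base + 1000L, phantom_eval = base + 2000L,
       voxel_sampling = base + 3000L, cnn_subsample = base + 4000L,
       folds = base + 5000L, network = base + 6000L, training = base + 7000L,
       bootstrap = base + 8000L)
}

# stage-1 inference on one phantom: features -> likelihood -> matched
# candidates; returns candidates plus the pieces later stages reuse
.detectOnPhantom <- function(phantom, model, cfg) {
  fs <- buildFeatureStack(phantom, cfg$features$scales_mm,
                          hessian_channel = cfg$features$hessian_channel)
  lik <- predictLikelihood(model, fs)
  cand <- detectCandidates(lik, cfg$stage1$window_diameter_mm,
                           cfg$stage1$floor)
  cand <- matchCandidates(cand, annotation(phantom))
  norm_t1 <- featureMap(fs, "t1_intensity")
  list(candidates = cand, normalized_t1 = norm_t1,
       n_nodes = nrow(nodeProperties(annotation(phantom))))
}

# fit the stage-1 boost model from a list of training phantoms
.trainStage1 <- function(phantoms, cfg, seed) {
  Xs <- list(); ys <- list()
  for (i in seq_along(phantoms)) {
    fs <- buildFeatureStack(phantoms[[i]], cfg$features$scales_mm,
                            hessian_channel = cfg$features$hessian_channel)
    ts <- buildVoxelTrainingSet(fs, annotation(phantoms[[i]]),
                                n_per_class = cfg$stage1$n_per_class,
                                min_volume_ml = cfg$stage1$min_volume_ml,
                                cog_radius_mm = cfg$stage1$cog_radius_mm,
                                seed = seed + i)
    Xs[[i]] <- ts$X; ys[[i]] <- ts$y
  }
  fitGentleBoost(do.call(rbind, Xs), unlist(ys),
                 n_rounds = cfg$stage1$n_rounds)
}

#' Run the full stage-1 versus multi-view-CNN comparison on phantoms
#'
#' Generates a training and an evaluation set of phantoms, trains the
#' stage-1 voxel classifier on the training phantoms, detects candidates on
#' every evaluation phantom, trains the \code{n_views}-view CNN with
#' stratified patient-level k-fold cross-validation (3 folds train, 1
#' validates, 1 tests per run; test-fold scores are pooled), and evaluates
#' both systems -- candidate detector alone versus CNN-rescored -- with
#' bootstrapped FROC/pAUC analysis and a one-sided paired bootstrap test.
#'
#' @param config a \code{\link{pipelineConfig}} (possibly modified).
#' @param n_eval,n_train number of evaluation / stage-1-training phantoms
#'   (override \code{config$simulate}).
#' @param verbose print progress.
#' @return list: \code{pauc} (per-system point estimate + CI),
#'   \code{p_comparison} (one-sided, Bonferroni-adjustable), \code{fp_at_target}
#'   (FP/image at the target sensitivity per system), \code{curves},
#'   \code{bootstrap}, \code{candidates} (per-phantom scored tables),
#'   \code{stage1_model}, \code{cv} (fold assignment and histories).
#' @export
runComparisonExperiment <- function(config = pipelineConfig(),
                                    n_eval = NULL, n_train = NULL,
                                    verbose = interactive()) {
  cfg <- config
  if (is.null(n_eval)) n_eval <- cfg$simulate$n_phantoms
  if (is.null(n_train)) n_train <- cfg$simulate$n_train
  seeds <- .fanSeeds(cfg$seed)
  say <- function(...) if (verbose) message(sprintf(...))

  say("generating %d training + %d evaluation phantom(s)", n_train, n_eval)
  train_ph <- lapply(seq_len(n_train), function(i) {
    pc <- cfg$phantom; pc$seed <- seeds$phantom_train + i
    generatePhantom(pc)
  })
  eval_ph <- lapply(seq_len(n_eval), function(i) {
    pc <- cfg$phantom; pc$seed <- seeds$phantom_eval + i
    generatePhantom(pc)
  })

  say("training stage-1 GentleBoost (%d rounds)", cfg$stage1$n_rounds)
  model1 <- .trainStage1(train_ph, cfg, seeds$voxel_sampling)

  say("detecting candidates on %d evaluation phantom(s)", n_eval)
  det <- lapply(eval_ph, .detectOnPhantom, model = model1, cfg = cfg)

  n_views <- cfg$multiview$n_views
  size <- cfg$multiview$size
  per <- vector("list", n_eval)
  for (i in seq_len(n_eval)) {
    cand <- det[[i]]$candidates
    ts <- buildCnnTrainingSet(cand, annotation(eval_ph[[i]]),
                              fp_subsample = cfg$cnn_fp_subsample,
                              seed = seeds$cnn_subsample + i)
    fn <- ts[ts$source == "fn", , drop = FALSE]
    entries <- data.frame(
      pos_mm_x = c(cand$pos_mm_x, fn$pos_mm_x),
      pos_mm_y = c(cand$pos_mm_y, fn$pos_mm_y),
      pos_mm_z = c(cand$pos_mm_z, fn$pos_mm_z))
    ts_entry <- integer(nrow(ts))
    fn_seen <- 0L
    for (r in seq_len(nrow(ts))) {
      if (ts$source[r] == "fn") {
        fn_seen <- fn_seen + 1L
        ts_entry[r] <- nrow(cand) + fn_seen
      } else ts_entry[r] <- ts$candidate_row[r]
    }
    patches <- candidatePatchArray(det[[i]]$normalized_t1, entries,
                                   n_views = n_views, size = size)
    per[[i]] <- list(candidates = cand, train_rows = ts_entry,
                     train_labels = ts$label, patches = patches,
                     n_nodes = det[[i]]$n_nodes)
  }

  node_counts <- vapply(per, `[[`, numeric(1), "n_nodes")
  names(node_counts) <- sprintf("phantom%02d", seq_len(n_eval))
  folds <- stratifiedPatientFolds(node_counts, k = 5L, seed = seeds$folds)
  say("cross-validating the %d-view CNN (5 runs)", n_views)

  histories <- list()
  for (run in seq_len(nrow(folds$schedule))) {
    test_f <- folds$schedule$test_fold[run]
    val_f <- folds$schedule$val_fold[run]
    tr_idx <- which(!folds$fold %in% c(test_f, val_f))
    va_idx <- which(folds$fold == val_f)
    te_idx <- which(folds$fold == test_f)
    gather <- function(idx) {
      ps <- lapply(idx, function(i)
        per[[i]]$patches[, , , per[[i]]$train_rows, drop = FALSE])
      lb <- unlist(lapply(idx, function(i) per[[i]]$train_labels))
      n <- sum(vapply(ps, function(p) dim(p)[4], numeric(1)))
      arr <- array(0, c(size, size, n_views, n))
      at <- 0L
      for (p in ps) {
        k <- dim(p)[4]
        if (k) arr[, , , at + seq_len(k)] <- p
        at <- at + k
      }
      list(patches = arr, labels = lb)
    }
    tr <- gather(tr_idx)
    va <- gather(va_idx)
    net <- buildNetwork(networkSpec(n_views = n_views, input_size = size),
                        seed = seeds$network + run)
    tc <- cfg$cnn
    tc$seed <- seeds$training + run
    fit <- trainNetwork(net, tr$patches, tr$labels, va$patches, va$labels,
                        config = tc)
    histories[[run]] <- fit$history
    say("  run %d: best val accuracy %.3f (epoch %d)", run,
        fit$best_val_accuracy, fit$best_epoch)
    for (i in te_idx) {
      nc <- nrow(per[[i]]$candidates)
      if (nc) {
        p <- scoreCandidates(fit$model,
                             per[[i]]$patches[, , , seq_len(nc), drop = FALSE])
        per[[i]]$candidates$cnn_probability <- p
      } else per[[i]]$candidates$cnn_probability <- numeric(0)
    }
  }

  sys_stage1 <- lapply(per, function(x)
    list(scores = x$candidates$likelihood,
         node_label = x$candidates$node_label, n_nodes = x$n_nodes))
  sys_cnn <- lapply(per, function(x)
    list(scores = x$candidates$cnn_probability,
         node_label = x$candidates$node_label, n_nodes = x$n_nodes))
  systems <- list(candidate_detector = sys_stage1)
  systems[[sprintf("cnn_%dview", n_views)]] <- sys_cnn

  say("bootstrapping FROC (%d replicates)", cfg$eval$n_boot)
  boot <- bootstrapFROC(systems, n_boot = cfg$eval$n_boot,
                        fp_range = cfg$eval$fp_range,
                        seed = seeds$bootstrap)
  cmp <- compareSystems(boot$pauc_reps[, 1], boot$pauc_reps[, 2],
                        n_comparisons = 1L)
  fp80 <- vapply(boot$curves, fpAtSensitivity, numeric(1),
                 sensitivity = cfg$eval$sensitivity_target, per = "image")

  list(pauc = boot$pauc, p_comparison = cmp, fp_at_target = fp80,
       sensitivity_target = cfg$eval$sensitivity_target,
       curves = boot$curves, bootstrap = boot,
       candidates = lapply(per, `[[`, "candidates"),
       n_nodes = node_counts, stage1_model = model1,
       cv = list(folds = folds, histories = histories))
}

# ---------------------------------------------------------------- CLI ops

#' Simulate a phantom dataset on disk
#'
#' Writes \code{n} phantoms (both channels plus the annotation label map as
#' NIfTI) and a manifest JSON listing every file with its MD5 checksum.
#' Phantoms are assigned the roles \code{"train"} (stage-1 training) and
#' \code{"eval"} according to \code{config$simulate}. Deterministic per
#' seed.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param out_dir output directory (created if missing).
#' @return the manifest, invisibly.
#' @export
runSimulate <- function(config = pipelineConfig(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("I/O error: cannot write ", out_dir)
  seeds <- .fanSeeds(config$seed)
  n_tr <- config$simulate$n_train
  n_ev <- config$simulate$n_phantoms
  entries <- list()
  make <- function(role, i, seed) {
    pc <- config$phantom; pc$seed <- seed
    ph <- generatePhantom(pc)
    id <- sprintf("%s_%03d", role, i)
    files <- c(t1 = file.path(out_dir, paste0(id, "_t1.nii.gz")),
               t2star = file.path(out_dir, paste0(id, "_t2star.nii.gz")),
               annotation = file.path(out_dir, paste0(id, "_annotation.nii.gz")))
    writeVolume(channel(ph, "t1"), files["t1"])
    writeVolume(channel(ph, "t2star"), files["t2star"])
    writeVolume(annotation(ph), files["annotation"], datatype = "int16")
    list(id = id, role = role, seed = seed,
         n_nodes = nrow(ph@nodeTable),
         files = setNames(as.list(basename(unname(files))), names(files)),
         md5 = setNames(as.list(unname(tools::md5sum(files))), names(files)))
  }
  for (i in seq_len(n_tr))
    entries[[length(entries) + 1L]] <- make("train", i, seeds$phantom_train + i)
  for (i in seq_len(n_ev))
    entries[[length(entries) + 1L]] <- make("eval", i, seeds$phantom_eval + i)
  manifest <- list(seed = config$seed, spacing_mm = config$phantom$spacing_mm,
                   n_train = n_tr, n_eval = n_ev, entries = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  yaml::write_yaml(rapply(config, unclass, how = "replace"),
                   file.path(out_dir, "config.yaml"))
  invisible(manifest)
}

.loadPhantomEntry <- function(dataset_dir, entry) {
  f <- function(which) readVolume(file.path(dataset_dir, entry$files[[which]]))
  t1 <- f("t1"); t2 <- f("t2star")
  annv <- f("annotation")
  ann <- ImageVolume(array(as.integer(round(voxelData(annv))), dim(annv)),
                     spacing(annv))
  list(t1 = t1, t2star = t2, annotation = ann, id = entry$id)
}

#' Detect candidates for every evaluation phantom of a dataset
#'
#' Trains the stage-1 voxel classifier on the dataset's training phantoms
#' (unless \code{model_path} points to an existing model JSON) and writes a
#' matched candidate CSV per evaluation phantom plus the model.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param dataset_dir directory produced by \code{\link{runSimulate}}.
#' @param out_dir output directory.
#' @param model_path optional serialized \linkS4class{BoostModel}.
#' @return data.frame summarizing per-image candidate counts, invisibly.
#' @export
runDetect <- function(config = pipelineConfig(), dataset_dir, out_dir,
                      model_path = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- jsonlite::read_json(file.path(dataset_dir, "manifest.json"),
                                  simplifyVector = FALSE)
  seeds <- .fanSeeds(config$seed)
  cfg <- config
  roles <- vapply(manifest$entries, `[[`, character(1), "role")
  if (is.null(model_path)) {
    tr_entries <- manifest$entries[roles == "train"]
    if (!length(tr_entries))
      stop("usage error: no trained model and no training phantoms in the dataset")
    phantoms <- lapply(tr_entries, function(e) {
      p <- .loadPhantomEntry(dataset_dir, e)
      props <- nodeProperties(p$annotation)
      # equivalent-sphere diameter stands in for the generator's record
      nt <- data.frame(label = props$label,
                       diameter_mm = (6 * props$volume_ml * 1000 / pi)^(1 / 3),
                       center_x_mm = props$cog_x_mm,
                       center_y_mm = props$cog_y_mm,
                       center_z_mm = props$cog_z_mm)
      new("Phantom", t1 = p$t1, t2star = p$t2star, annotation = p$annotation,
          nodeTable = nt, config = phantomConfig())
    })
    model <- .trainStage1(phantoms, cfg, seeds$voxel_sampling)
    writeBoostModel(model, file.path(out_dir, "stage1_model.json"))
  } else model <- readBoostModel(model_path)
  summary <- data.frame(id = character(0), n_candidates = integer(0))
  for (e in manifest$entries[roles == "eval"]) {
    p <- .loadPhantomEntry(dataset_dir, e)
    fs <- buildFeatureStack(list(t1 = p$t1, t2star = p$t2star),
                            cfg$features$scales_mm,
                            hessian_channel = cfg$features$hessian_channel)
    lik <- predictLikelihood(model, fs)
    cand <- detectCandidates(lik, cfg$stage1$window_diameter_mm,
                             cfg$stage1$floor)
    cand <- matchCandidates(cand, p$annotation)
    writeCandidates(cand, file.path(out_dir, paste0(e$id, "_candidates.csv")))
    message(sprintf("%s: %d candidate(s)", e$id, nrow(cand)))
    summary <- rbind(summary, data.frame(id = e$id, n_candidates = nrow(cand)))
  }
  invisible(summary)
}

#' Rescore candidates with the cross-validated multi-view CNN
#'
#' Runs stratified patient-level 5-fold cross-validation of the
#' \code{n_views}-view network over the evaluation phantoms and writes each
#' phantom's candidates with the pooled test-fold \code{cnn_probability}.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param dataset_dir dataset from \code{\link{runSimulate}}.
#' @param candidates_dir candidate CSVs from \code{\link{runDetect}}.
#' @param out_dir output directory.
#' @param n_views 1, 3 or 9 (defaults to the config).
#' @return data.frame of per-run best validation accuracies, invisibly.
#' @export
runReduceFP <- function(config = pipelineConfig(), dataset_dir,
                        candidates_dir, out_dir, n_views = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- jsonlite::read_json(file.path(dataset_dir, "manifest.json"),
                                  simplifyVector = FALSE)
  cfg <- config
  if (is.null(n_views)) n_views <- cfg$multiview$n_views
  seeds <- .fanSeeds(cfg$seed)
  size <- cfg$multiview$size
  roles <- vapply(manifest$entries, `[[`, character(1), "role")
  evals <- manifest$entries[roles == "eval"]
  per <- vector("list", length(evals))
  for (i in seq_along(evals)) {
    e <- evals[[i]]
    p <- .loadPhantomEntry(dataset_dir, e)
    cand <- readCandidates(file.path(candidates_dir,
                                     paste0(e$id, "_candidates.csv")))
    if (!"node_label" %in% names(cand))
      cand <- matchCandidates(cand, p$annotation)
    ts <- buildCnnTrainingSet(cand, p$annotation,
                              fp_subsample = cfg$cnn_fp_subsample,
                              seed = seeds$cnn_subsample + i)
    fn <- ts[ts$source == "fn", , drop = FALSE]
    entries <- data.frame(pos_mm_x = c(cand$pos_mm_x, fn$pos_mm_x),
                          pos_mm_y = c(cand$pos_mm_y, fn$pos_mm_y),
                          pos_mm_z = c(cand$pos_mm_z, fn$pos_mm_z))
    ts_entry <- integer(nrow(ts)); fn_seen <- 0L
    for (r in seq_len(nrow(ts))) {
      if (ts$source[r] == "fn") {
        fn_seen <- fn_seen + 1L
        ts_entry[r] <- nrow(cand) + fn_seen
      } else ts_entry[r] <- ts$candidate_row[r]
    }
    norm_t1 <- normalizeIntensity(p$t1)
    per[[i]] <- list(id = e$id, candidates = cand,
                     patches = candidatePatchArray(norm_t1, entries,
                                                   n_views, size),
                     train_rows = ts_entry, train_labels = ts$label,
                     n_nodes = nrow(nodeProperties(p$annotation)))
  }
  node_counts <- vapply(per, `[[`, numeric(1), "n_nodes")
  names(node_counts) <- vapply(per, `[[`, character(1), "id")
  folds <- stratifiedPatientFolds(node_counts, k = 5L, seed = seeds$folds)
  runs <- data.frame(run = integer(0), best_val_accuracy = numeric(0))
  for (run in seq_len(nrow(folds$schedule))) {
    test_f <- folds$schedule$test_fold[run]
    val_f <- folds$schedule$val_fold[run]
    tr_idx <- which(!folds$fold %in% c(test_f, val_f))
    va_idx <- which(folds$fold == val_f)
    gather <- function(idx) {
      lb <- unlist(lapply(idx, function(i) per[[i]]$train_labels))
      n <- length(lb)
      arr <- array(0, c(size, size, n_views, n))
      at <- 0L
      for (i in idx) {
        rows <- per[[i]]$train_rows
        if (length(rows))
          arr[, , , at + seq_along(rows)] <- per[[i]]$patches[, , , rows, drop = FALSE]
        at <- at + length(rows)
      }
      list(patches = arr, labels = lb)
    }
    tr <- gather(tr_idx); va <- gather(va_idx)
    if (length(unique(tr$labels)) < 2 || length(unique(va$labels)) < 2)
      stop(sprintf("fold error: run %d has a single-class training or validation fold", run))
    net <- buildNetwork(networkSpec(n_views = n_views, input_size = size),
                        seed = seeds$network + run)
    tc <- cfg$cnn; tc$seed <- seeds$training + run
    fit <- trainNetwork(net, tr$patches, tr$labels, va$patches, va$labels,
                        config = tc)
    write.csv(fit$history,
              file.path(out_dir, sprintf("history_run%d.csv", run)),
              row.names = FALSE)
    runs <- rbind(runs, data.frame(run = run,
                                   best_val_accuracy = fit$best_val_accuracy))
    for (i in which(folds$fold == test_f)) {
      nc <- nrow(per[[i]]$candidates)
      per[[i]]$candidates$cnn_probability <-
        if (nc) scoreCandidates(fit$model,
                                per[[i]]$patches[, , , seq_len(nc), drop = FALSE])
        else numeric(0)
    }
  }
  for (x in per)
    writeCandidates(x$candidates,
                    file.path(out_dir, paste0(x$id, "_candidates.csv")))
  invisible(runs)
}

#' Evaluate one or more scored candidate sets
#'
#' Builds the pooled FROC curve per system, bootstraps confidence bands and
#' partial AUCs on the shared patient resamples, performs all pairwise
#' one-sided comparisons with Bonferroni correction, and writes curves
#' (CSV) and a report (JSON).
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param system_dirs named character vector of directories containing
#'   per-phantom scored candidate CSVs.
#' @param dataset_dir dataset directory (for annotations / node counts).
#' @param out_dir output directory.
#' @param score_columns score column per system (recycled); use
#'   \code{"likelihood"} for the raw candidate detector and
#'   \code{"cnn_probability"} for rescored sets.
#' @return the report list, invisibly.
#' @export
runEvaluate <- function(config = pipelineConfig(), system_dirs, dataset_dir,
                        out_dir, score_columns = "cnn_probability") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- jsonlite::read_json(file.path(dataset_dir, "manifest.json"),
                                  simplifyVector = FALSE)
  roles <- vapply(manifest$entries, `[[`, character(1), "role")
  evals <- manifest$entries[roles == "eval"]
  if (is.null(names(system_dirs)))
    names(system_dirs) <- paste0("system", seq_along(system_dirs))
  score_columns <- rep_len(score_columns, length(system_dirs))
  n_nodes_per <- vapply(evals, function(e) as.integer(e$n_nodes), integer(1))
  systems <- lapply(seq_along(system_dirs), function(k) {
    lapply(seq_along(evals), function(i) {
      cand <- readCandidates(file.path(system_dirs[k],
                                       paste0(evals[[i]]$id, "_candidates.csv")))
      if (!score_columns[k] %in% names(cand))
        stop("system '", names(system_dirs)[k], "' lacks a '",
             score_columns[k], "' column for ", evals[[i]]$id)
      list(scores = cand[[score_columns[k]]],
           node_label = cand$node_label, n_nodes = n_nodes_per[i])
    })
  })
  names(systems) <- names(system_dirs)
  seeds <- .fanSeeds(config$seed)
  boot <- bootstrapFROC(systems, n_boot = config$eval$n_boot,
                        fp_range = config$eval$fp_range,
                        seed = seeds$bootstrap)
  m <- length(systems) * (length(systems) - 1) / 2
  pvals <- list()
  if (m >= 1) {
    for (a in seq_along(systems)) for (b in seq_along(systems)) {
      if (b <= a) next
      cmp <- compareSystems(boot$pauc_reps[, a], boot$pauc_reps[, b],
                            n_comparisons = m)
      pvals[[paste0(names(systems)[b], "_vs_", names(systems)[a])]] <- cmp
    }
  }
  for (k in seq_along(systems))
    writeFROCCurve(boot$curves[[k]],
                   file.path(out_dir, paste0("froc_", names(systems)[k], ".csv")),
                   bands = boot$bands[[k]])
  fp80 <- vapply(boot$curves, fpAtSensitivity, numeric(1),
                 sensitivity = config$eval$sensitivity_target, per = "image")
  report <- list(pauc = boot$pauc, p_values = pvals,
                 fp_per_image_at_target_sensitivity = as.list(fp80),
                 sensitivity_target = config$eval$sensitivity_target,
                 n_boot = boot$n_boot, fp_range = boot$fp_range,
                 seed = config$seed)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(report)
}
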