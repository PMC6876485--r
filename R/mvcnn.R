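# Multi-view CNN for false-positive reduction: one convolutional branch per
# view, feature concatenation, hidden FC layer, 2-way softmax.

#' Architecture specification of the multi-view network
#'
#' The per-view branch is conv(5x5, 24) -> maxpool(2x2, stride 2) ->
#' conv(5x5, 48) -> maxpool(2x2, stride 2) -> conv(5x5, 96), with ReLU
#' nonlinearities, stride-1 valid convolutions and no padding; branch
#' outputs are concatenated along the feature dimension and fed to a
#' 512-unit fully-connected ReLU layer and a 2-way softmax. For a 65 x 65
#' input the per-view spatial trace is 61 -> 30 -> 26 -> 13 -> 9.
#'
#' @param n_views 1, 3 or 9 (one branch per view; weights are not shared).
#' @param input_size patch side in samples.
#' @param conv_channels channels of the three convolutional layers.
#' @param fc_units width of the hidden fully-connected layer.
#' @param kernel convolution kernel side.
#' @return list of class \code{NetworkSpec}.
#' @export
networkSpec <- function(n_views = 3L, input_size = 65L,
                        conv_channels = c(24L, 48L, 96L), fc_units = 512L,
                        kernel = 5L) {
  if (!n_views %in% c(1L, 3L, 9L))
    stop("config error: n_views must be 1, 3 or 9")
  stopifnot(length(conv_channels) == 3, input_size >= 3, kernel >= 3)
  out <- list(n_views = as.integer(n_views),
              input_size = as.integer(input_size),
              conv_channels = as.integer(conv_channels),
              fc_units = as.integer(fc_units), kernel = as.integer(kernel))
  class(out) <- "NetworkSpec"
  out
}

#' Analytic per-view shape trace of the network
#'
#' Computes the spatial size and channel count after every layer for a given
#' input size, using valid stride-1 convolutions (size \code{n - k + 1}) and
#' 2x2 stride-2 pooling (size \code{floor((n - 2)/2) + 1}).
#'
#' @param spec a \code{\link{networkSpec}}.
#' @return data.frame with columns layer, type, width, height, channels.
#' @examples
#' networkShapeTrace(networkSpec(3))
#' @export
networkShapeTrace <- function(spec = networkSpec()) {
  n <- spec$input_size
  k <- spec$kernel
  ch <- spec$conv_channels
  sizes <- integer(0)
  conv <- function(n) n - k + 1L
  pool <- function(n) (n - 2L) %/% 2L + 1L
  c1 <- conv(n); p1 <- pool(c1); c2 <- conv(p1); p2 <- pool(c2); c3 <- conv(p2)
  if (c3 < 1) stop("config error: input too small for the layer stack")
  data.frame(
    layer = 1:8,
    type = c("input", "conv", "maxpool", "conv", "maxpool", "conv",
             "fc", "softmax"),
    width = c(n, c1, p1, c2, p2, c3, 1L, 1L),
    height = c(n, c1, p1, c2, p2, c3, 1L, 1L),
    channels = c(1L, ch[1], ch[1], ch[2], ch[2], ch[3],
                 spec$fc_units, 2L))
}

# He-uniform initialization: U(-sqrt(6/fan_in), +sqrt(6/fan_in))
.heUniform <- function(nrow, ncol, fan_in) {
  lim <- sqrt(6 / fan_in)
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

#' Build (initialize) a multi-view network
#'
#' Creates one independent weight set per view branch (no weight sharing),
#' He-uniform initialization for convolutional and fully-connected weights,
#' zero biases. Deterministic for a fixed seed.
#'
#' @param spec a \code{\link{networkSpec}}.
#' @param seed RNG seed for the initialization.
#' @return An \linkS4class{MVCNNModel}.
#' @export
buildNetwork <- function(spec = networkSpec(), seed = 1L) {
  tr <- networkShapeTrace(spec)
  k <- spec$kernel
  ch <- spec$conv_channels
  o3 <- tr$width[tr$layer == 6]
  D <- spec$n_views * ch[3] * o3 * o3
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  views <- lapply(seq_len(spec$n_views), function(v) {
    list(W1 = .heUniform(ch[1], k * k, k * k), b1 = numeric(ch[1]),
         W2 = .heUniform(ch[2], ch[1] * k * k, ch[1] * k * k),
         b2 = numeric(ch[2]),
         W3 = .heUniform(ch[3], ch[2] * k * k, ch[2] * k * k),
         b3 = numeric(ch[3]))
  })
  weights <- list(views = views,
                  fc1W = .heUniform(spec$fc_units, D, D),
                  fc1b = numeric(spec$fc_units),
                  fc2W = .heUniform(2L, spec$fc_units, spec$fc_units),
                  fc2b = numeric(2))
  new("MVCNNModel", spec = unclass(spec), weights = weights)
}

#' Total number of trainable parameters
#'
#' @param model an \linkS4class{MVCNNModel}.
#' @return integer count.
#' @export
parameterCount <- function(model) {
  sum(rapply(model@weights, length, how = "unlist"))
}

#' Training configuration for the multi-view network
#'
#' Defaults are the reference training protocol: plain SGD with learning
#' rate 1e-4 and Nesterov momentum 0.9; categorical cross-entropy with an
#' L2 penalty of 5e-4 on the weight matrices; 20\% dropout on the hidden
#' fully-connected layer; minibatches of 32 multi-view patch sets with a
#' balanced class distribution (16 + 16, sampled with replacement); an
#' epoch is 200 minibatches; training runs at most 200 epochs and stops
#' early when validation accuracy has not improved for more than 20 epochs,
#' returning the best-validation-accuracy weights.
#'
#' @param learning_rate,nesterov_momentum,l2_lambda,dropout_fc,batch_size
#'   optimizer and regularization settings.
#' @param minibatches_per_epoch,max_epochs,early_stop_patience_epochs
#'   schedule settings.
#' @param seed RNG seed for batch sampling and dropout.
#' @return list of class \code{TrainConfig}.
#' @export
trainConfig <- function(learning_rate = 1e-4, nesterov_momentum = 0.9,
                        l2_lambda = 5e-4, dropout_fc = 0.2,
                        batch_size = 32L, minibatches_per_epoch = 200L,
                        max_epochs = 200L,
                        early_stop_patience_epochs = 20L, seed = 1L) {
  stopifnot(learning_rate > 0, nesterov_momentum >= 0, l2_lambda >= 0,
            dropout_fc >= 0, dropout_fc < 1, batch_size > 0,
            minibatches_per_epoch > 0, max_epochs > 0,
            early_stop_patience_epochs >= 0)
  out <- list(learning_rate = learning_rate,
              nesterov_momentum = nesterov_momentum, l2_lambda = l2_lambda,
              dropout_fc = dropout_fc, batch_size = as.integer(batch_size),
              minibatches_per_epoch = as.integer(minibatches_per_epoch),
              max_epochs = as.integer(max_epochs),
              early_stop_patience_epochs = as.integer(early_stop_patience_epochs),
              seed = as.integer(seed))
  class(out) <- "TrainConfig"
  out
}

#' Label candidates for CNN training
#'
#' The network is trained with all lymph nodes -- true positives and
#' stage-1 false negatives -- and a random subset of stage-1 false
#' positives. Positives are every matched candidate position plus, for
#' every annotated node without a matching candidate, the node's center of
#' gravity; negatives are a seeded random subset of the false-positive
#' candidates.
#'
#' @param candidates matched candidates (see \code{\link{matchCandidates}}),
#'   i.e. with a \code{node_label} column.
#' @param annotation the label-map \linkS4class{ImageVolume}.
#' @param fp_subsample fraction (<= 1) or count (> 1) of false positives to
#'   retain.
#' @param seed RNG seed for the subsample.
#' @return data.frame with \code{pos_mm_x/y/z}, \code{label} (1 = node),
#'   \code{source} ("tp", "fn", "fp") and, for candidate rows, the original
#'   candidate row index \code{candidate_row}.
#' @export
buildCnnTrainingSet <- function(candidates, annotation, fp_subsample = 1.0,
                                seed = 1L) {
  stopifnot(is.data.frame(candidates), "node_label" %in% names(candidates))
  props <- nodeProperties(annotation)
  tp <- candidates[!is.na(candidates$node_label), , drop = FALSE]
  fp <- candidates[is.na(candidates$node_label), , drop = FALSE]
  missed <- props[!props$label %in% tp$node_label, , drop = FALSE]
  n_pos <- nrow(tp) + nrow(missed)
  if (n_pos == 0)
    stop("zero positives: no annotated nodes available for CNN training")
  pos <- data.frame(
    pos_mm_x = c(tp$pos_mm_x, missed$cog_x_mm),
    pos_mm_y = c(tp$pos_mm_y, missed$cog_y_mm),
    pos_mm_z = c(tp$pos_mm_z, missed$cog_z_mm),
    label = rep(1L, n_pos),
    source = c(rep("tp", nrow(tp)), rep("fn", nrow(missed))),
    candidate_row = c(as.integer(rownames(tp)), rep(NA_integer_, nrow(missed))))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  n_fp <- if (fp_subsample <= 1) round(fp_subsample * nrow(fp)) else min(fp_subsample, nrow(fp))
  take <- if (n_fp < nrow(fp)) sort(sample(nrow(fp), n_fp)) else seq_len(nrow(fp))
  neg <- data.frame(
    pos_mm_x = fp$pos_mm_x[take], pos_mm_y = fp$pos_mm_y[take],
    pos_mm_z = fp$pos_mm_z[take], label = 0L,
    source = rep("fp", length(take)),
    candidate_row = as.integer(rownames(fp))[take])
  out <- rbind(pos, neg)
  rownames(out) <- NULL
  out
}

#' Train the multi-view network
#'
#' Minibatch SGD with Nesterov momentum on categorical cross-entropy plus
#' an L2 penalty on the weight matrices. Every minibatch contains equal
#' numbers of node and non-node patch sets, sampled with replacement.
#' Validation accuracy (threshold 0.5) is computed on the full validation
#' set at the end of each epoch; training stops at \code{max_epochs} or
#' when validation accuracy has not improved for more than the patience,
#' and the returned model carries the best-validation-accuracy weights.
#'
#' @param model an \linkS4class{MVCNNModel}.
#' @param train_patches array \code{[s, s, n_views, n]} of training patch
#'   sets.
#' @param train_labels integer 0/1 labels (1 = node).
#' @param val_patches,val_labels validation set in the same format.
#' @param config a \code{\link{trainConfig}}.
#' @param log_batch_classes if TRUE, record per-minibatch positive counts
#'   (for auditing the balanced sampling).
#' @return list: \code{model} (trained \linkS4class{MVCNNModel}),
#'   \code{history} (epoch, train_loss, val_accuracy), \code{best_epoch},
#'   \code{best_val_accuracy}, and optionally \code{batch_pos_counts}.
#' @export
trainNetwork <- function(model, train_patches, train_labels, val_patches,
                         val_labels, config = trainConfig(),
                         log_batch_classes = FALSE) {
  stopifnot(is(model, "MVCNNModel"))
  train_labels <- as.integer(train_labels)
  val_labels <- as.integer(val_labels)
  if (length(unique(train_labels)) < 2 || length(unique(val_labels)) < 2)
    stop("both classes must be present in the training and validation sets")
  if (dim(train_patches)[3] != model@spec$n_views)
    stop("patch view count does not match the network")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  cfg <- c(unclass(config), list(log_batch_classes = isTRUE(log_batch_classes)))
  res <- .cnnTrain(model@weights, train_patches, train_labels, val_patches,
                   val_labels, cfg)
  out <- list(model = new("MVCNNModel", spec = model@spec,
                          weights = res$weights),
              history = res$history, best_epoch = res$best_epoch,
              best_val_accuracy = res$best_val_accuracy)
  if (isTRUE(log_batch_classes)) out$batch_pos_counts <- res$batch_pos_counts
  out
}

#' Score candidate patch sets with the network
#'
#' @param model a trained \linkS4class{MVCNNModel}.
#' @param patches array \code{[s, s, n_views, n]}.
#' @param trace if TRUE, also return the per-layer shape trace of the
#'   forward pass.
#' @return numeric vector of node-class softmax probabilities (or a list
#'   with \code{probabilities} and \code{trace} when \code{trace = TRUE}).
#' @export
scoreCandidates <- function(model, patches, trace = FALSE) {
  stopifnot(is(model, "MVCNNModel"))
  if (length(dim(patches)) == 3)
    dim(patches) <- c(dim(patches), 1L)
  if (dim(patches)[4] == 0) {
    if (trace) stop("cannot trace an empty batch")
    return(numeric(0))
  }
  res <- .cnnPredict(model@weights, patches, trace)
  p <- res$probs[, 2]
  if (trace) list(probabilities = p, trace = res$trace) else p
}
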