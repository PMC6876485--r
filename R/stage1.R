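# Stage 1: GentleBoost voxel classification and candidate extraction.

#' Build the balanced voxel training set for the stage-1 classifier
#'
#' Positive rows are drawn only from voxels of lymph nodes with a volume of
#' at least \code{min_volume_ml}, and only within \code{cog_radius_mm} of
#' that node's center of gravity (excluding boundary voxels guards against
#' partial-volume and annotation errors). Negative rows are drawn uniformly
#' from background voxels. Class counts are equal, and sampling is
#' deterministic for a fixed seed.
#'
#' @param features a \linkS4class{FeatureStack}.
#' @param annotation label-map \linkS4class{ImageVolume} on the same grid.
#' @param n_per_class rows per class; capped by availability.
#' @param min_volume_ml nodes below this volume are excluded (0.1 ml is
#'   approximately 195 voxels at 0.8 mm).
#' @param cog_radius_mm positive voxels must lie within this distance of the
#'   node's center of gravity.
#' @param seed RNG seed for the row sampling.
#' @return list with \code{X} (matrix, one row per voxel), \code{y}
#'   (labels in -1/+1), and \code{voxel} (linear voxel indices).
#' @export
buildVoxelTrainingSet <- function(features, annotation, n_per_class = 2000L,
                                  min_volume_ml = 0.1, cog_radius_mm = 4,
                                  seed = 1L) {
  stopifnot(is(features, "FeatureStack"), is(annotation, "ImageVolume"))
  dims <- dim(features@maps)[1:3]
  if (!identical(dims, dim(annotation)))
    stop("features and annotation must share the grid")
  s <- spacing(annotation)
  a <- voxelData(annotation)
  props <- nodeProperties(annotation)
  eligible <- props[props$volume_ml >= min_volume_ml, , drop = FALSE]
  pos_idx <- integer(0)
  for (r in seq_len(nrow(eligible))) {
    l <- eligible$label[r]
    idx <- which(a == l)
    ai <- arrayInd(idx, dims)
    ctr <- c(eligible$cog_x_mm[r], eligible$cog_y_mm[r], eligible$cog_z_mm[r])
    d2 <- ((ai[, 1] - 0.5) * s - ctr[1])^2 + ((ai[, 2] - 0.5) * s - ctr[2])^2 +
      ((ai[, 3] - 0.5) * s - ctr[3])^2
    pos_idx <- c(pos_idx, idx[d2 <= cog_radius_mm^2])
  }
  if (!length(pos_idx))
    stop("empty-class error: no eligible positive voxels ",
         "(all nodes below ", min_volume_ml, " ml?)")
  bg_idx <- which(a == 0)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  n <- min(n_per_class, length(pos_idx), length(bg_idx))
  pos_take <- if (n < length(pos_idx)) sort(sample(pos_idx, n)) else pos_idx
  neg_take <- sort(sample(bg_idx, n))
  X <- featureMatrix(features)[c(pos_take, neg_take), , drop = FALSE]
  list(X = X,
       y = c(rep(1, length(pos_take)), rep(-1, length(neg_take))),
       voxel = c(pos_take, neg_take))
}

#' Fit a GentleBoost classifier with regression stumps
#'
#' Classic GentleBoost: observation weights start uniform; each round fits
#' the regression stump minimizing the weighted squared error to the labels
#' (each side's response is the weighted mean of \code{y} on that side,
#' thresholds searched at midpoints between consecutive distinct sorted
#' feature values), the stump is added to the additive score
#' \eqn{F \leftarrow F + f_m}, and weights are updated multiplicatively as
#' \eqn{w \leftarrow w\,e^{-y f_m}} and renormalized. Deterministic given
#' the input row order (ties broken towards the lowest feature index and
#' threshold).
#'
#' @param X numeric feature matrix (rows = examples).
#' @param y labels in \{-1, +1\}; both classes must be present.
#' @param n_rounds number of weak learners.
#' @return A \linkS4class{BoostModel}.
#' @export
fitGentleBoost <- function(X, y, n_rounds = 200L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  if (!all(y %in% c(-1, 1))) stop("labels must be -1/+1")
  if (length(unique(y)) < 2) stop("both classes must be present")
  n <- nrow(X); p <- ncol(X)
  ord <- lapply(seq_len(p), function(j) order(X[, j]))
  xs <- lapply(seq_len(p), function(j) X[ord[[j]], j])
  valid <- lapply(seq_len(p), function(j) {
    which(diff(xs[[j]]) > 0)  # split after position i
  })
  w <- rep(1 / n, n)
  stumps <- data.frame(feature_index = integer(n_rounds),
                       threshold = numeric(n_rounds),
                       response_ge = numeric(n_rounds),
                       response_lt = numeric(n_rounds))
  for (m in seq_len(n_rounds)) {
    best <- list(score = -Inf)
    for (j in seq_len(p)) {
      vi <- valid[[j]]
      if (!length(vi)) next
      wj <- w[ord[[j]]]
      yj <- y[ord[[j]]]
      cw <- cumsum(wj)
      cwy <- cumsum(wj * yj)
      W <- cw[n]; WY <- cwy[n]
      lw <- cw[vi]; ly <- cwy[vi]
      rw <- W - lw; ry <- WY - ly
      score <- ly^2 / lw + ry^2 / rw  # equivalent to minimizing weighted SSE
      k <- which.max(score)
      if (score[k] > best$score + 1e-15) {
        i <- vi[k]
        best <- list(score = score[k], feature = j,
                     threshold = (xs[[j]][i] + xs[[j]][i + 1]) / 2,
                     response_lt = ly[k] / lw[k],
                     response_ge = ry[k] / rw[k])
      }
    }
    if (!is.finite(best$score)) {  # no split possible (constant features)
      stumps <- stumps[seq_len(m - 1), , drop = FALSE]
      break
    }
    stumps$feature_index[m] <- best$feature
    stumps$threshold[m] <- best$threshold
    stumps$response_ge[m] <- best$response_ge
    stumps$response_lt[m] <- best$response_lt
    fm <- ifelse(X[, best$feature] >= best$threshold,
                 best$response_ge, best$response_lt)
    w <- w * exp(-y * fm)
    w <- w / sum(w)
  }
  fn <- colnames(X)
  if (is.null(fn)) fn <- paste0("f", seq_len(p))
  new("BoostModel", stumps = stumps, featureNames = fn,
      nRounds = as.integer(n_rounds))
}

#' Additive boosting score F(x) for feature rows
#'
#' @param model a \linkS4class{BoostModel}.
#' @param X numeric matrix in the model's feature space.
#' @return Numeric vector of raw scores (one per row).
#' @export
boostScore <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) < max(c(0L, stumps(model)$feature_index)))
    stop("feature matrix does not match the model's feature space")
  st <- stumps(model)
  .boostScore(X, as.integer(st$feature_index - 1L), st$threshold,
              st$response_ge, st$response_lt)
}

#' Per-voxel lymph node likelihood map
#'
#' Applies the boosted stump ensemble to every voxel and maps the raw
#' additive score to \eqn{[0, 1]} with the logistic link
#' \eqn{1 / (1 + e^{-2F})}, the standard calibration for additive logistic
#' boosting (an empty model yields 0.5 everywhere).
#'
#' @param model a \linkS4class{BoostModel}.
#' @param features a \linkS4class{FeatureStack} matching the model.
#' @return An \linkS4class{ImageVolume} of likelihoods in \eqn{[0, 1]}.
#' @export
predictLikelihood <- function(model, features) {
  stopifnot(is(model, "BoostModel"), is(features, "FeatureStack"))
  if (length(featureNames(model)) &&
      !identical(featureNames(model), featureNames(features)))
    stop("feature mismatch: model was fitted on ",
         paste(featureNames(model), collapse = ", "))
  FF <- boostScore(model, featureMatrix(features))
  L <- 1 / (1 + exp(-2 * FF))
  ImageVolume(array(L, dim(features@maps)[1:3]), spacing(features))
}

#' Detect candidates as spherical-window local maxima with plateau merging
#'
#' A voxel is a local maximum iff its likelihood is \eqn{\ge} that of every
#' voxel whose center lies within \code{window_diameter_mm / 2} (Euclidean,
#' default 10 mm diameter -- the maximum size of non-enlarged lymph nodes)
#' and exceeds \code{floor}. Plateau-shaped maxima are merged by
#' 26-connected component analysis: each component is reduced to the member
#' voxel nearest its center of gravity (ties broken by lexicographic voxel
#' index), carrying the plateau's likelihood.
#'
#' @param likelihood \linkS4class{ImageVolume} of per-voxel likelihoods.
#' @param window_diameter_mm spherical window diameter in mm.
#' @param floor candidates must exceed this likelihood (suppresses the
#'   all-background plateau).
#' @return data.frame of candidates sorted by decreasing likelihood:
#'   \code{index_x/y/z} (1-based voxel indices), \code{pos_mm_x/y/z}
#'   (voxel-center positions) and \code{likelihood}.
#' @export
detectCandidates <- function(likelihood, window_diameter_mm = 10,
                             floor = 0.01) {
  stopifnot(is(likelihood, "ImageVolume"))
  L <- voxelData(likelihood)
  if (any(L < 0 | L > 1)) stop("likelihood map must lie in [0, 1]")
  s <- spacing(likelihood)
  if (length(s) != 1) stop("unsupported input: anisotropic spacing")
  dims <- dim(L)
  vox <- .localMaximaSpherical(L, dims, s, window_diameter_mm / 2, floor)
  if (!length(vox)) {
    return(data.frame(index_x = integer(0), index_y = integer(0),
                      index_z = integer(0), pos_mm_x = numeric(0),
                      pos_mm_y = numeric(0), pos_mm_z = numeric(0),
                      likelihood = numeric(0)))
  }
  comp <- .labelComponents26(vox, dims)
  ai <- arrayInd(vox + 1L, dims)  # 1-based indices
  keep <- vapply(split(seq_along(vox), comp), function(members) {
    m <- ai[members, , drop = FALSE]
    ctr <- colMeans(m)
    d2 <- rowSums(sweep(m, 2, ctr)^2)
    o <- order(d2, m[, 1], m[, 2], m[, 3])
    members[o[1]]
  }, integer(1))
  idx <- ai[keep, , drop = FALSE]
  out <- data.frame(index_x = idx[, 1], index_y = idx[, 2],
                    index_z = idx[, 3],
                    pos_mm_x = (idx[, 1] - 0.5) * s,
                    pos_mm_y = (idx[, 2] - 0.5) * s,
                    pos_mm_z = (idx[, 3] - 0.5) * s,
                    likelihood = L[idx])
  out <- out[order(-out$likelihood, out$index_x, out$index_y, out$index_z), ]
  rownames(out) <- NULL
  out
}
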