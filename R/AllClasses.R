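#' ImageVolume: a 3D scalar grid with isotropic spacing
#'
#' Container for a single-channel 3D image on an isotropic voxel grid.
#' The world position of voxel index \code{i} (1-based) along any axis is
#' \code{(i - 0.5) * spacing} millimetres.
#'
#' @slot voxels 3D numeric array.
#' @slot spacing isotropic voxel size in mm (single positive number).
#' @export
setClass("ImageVolume",
         representation(voxels = "array", spacing = "numeric"))

setValidity("ImageVolume", function(object) {
  msg <- NULL
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "'voxels' must be a 3D array")
  if (length(object@spacing) != 1L || !is.finite(object@spacing) ||
      object@spacing <= 0)
    msg <- c(msg, "'spacing' must be a single positive number")
  if (is.null(msg)) TRUE else msg
})

#' Construct an ImageVolume
#'
#' @param voxels 3D numeric array.
#' @param spacing isotropic voxel size in mm.
#' @return An \linkS4class{ImageVolume}.
#' @examples
#' v <- ImageVolume(array(0, c(8, 8, 8)), spacing = 0.8)
#' dim(v)
#' @export
ImageVolume <- function(voxels, spacing = 0.8) {
  new("ImageVolume", voxels = voxels, spacing = spacing)
}

#' @describeIn ImageVolume grid dimensions (voxels per axis).
#' @param x an \code{ImageVolume}.
#' @export
setMethod("dim", "ImageVolume", function(x) dim(x@voxels))

#' Accessors for ImageVolume
#'
#' \code{voxelData} returns the raw 3D array; \code{spacing} the isotropic
#' voxel size in mm.
#'
#' @param object an \linkS4class{ImageVolume} (or \linkS4class{FeatureStack}
#'   for \code{spacing}).
#' @return \code{voxelData}: a 3D array. \code{spacing}: a number (mm).
#' @aliases voxelData spacing
#' @export
setGeneric("voxelData", function(object) standardGeneric("voxelData"))

#' @rdname voxelData
#' @export
setMethod("voxelData", "ImageVolume", function(object) object@voxels)

#' @rdname voxelData
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))

#' @rdname voxelData
#' @export
setMethod("spacing", "ImageVolume", function(object) object@spacing)

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageVolume: %d x %d x %d voxels @ %.3g mm (%.1f x %.1f x %.1f mm)\n",
              d[1], d[2], d[3], object@spacing,
              d[1] * object@spacing, d[2] * object@spacing,
              d[3] * object@spacing))
  cat(sprintf("  intensity range: [%.4g, %.4g]\n",
              min(object@voxels), max(object@voxels)))
})

#' Phantom: synthetic dual-channel MRL study with ground truth
#'
#' Two co-registered channels emulating a T1-weighted ("VIBE"-like) and a
#' T2*-weighted ("MEDIC"-like) acquisition, plus an integer annotation label
#' map in which voxels of lymph node \code{k} carry label \code{k}
#' (background 0).
#'
#' @slot t1 \linkS4class{ImageVolume}, T1-like channel.
#' @slot t2star \linkS4class{ImageVolume}, T2*-like channel.
#' @slot annotation \linkS4class{ImageVolume} holding the integer label map.
#' @slot nodeTable data.frame of per-node ground truth (label, center, size).
#' @slot config the \linkS4class{PhantomConfig} used to generate it.
#' @export
setClass("Phantom",
         representation(t1 = "ImageVolume", t2star = "ImageVolume",
                        annotation = "ImageVolume", nodeTable = "data.frame",
                        config = "ANY"))

setValidity("Phantom", function(object) {
  msg <- NULL
  if (!identical(dim(object@t1), dim(object@t2star)) ||
      !identical(dim(object@t1), dim(object@annotation)))
    msg <- c(msg, "channels and annotation must share the grid")
  if (!isTRUE(all.equal(spacing(object@t1), spacing(object@t2star))))
    msg <- c(msg, "channels must share spacing")
  labs <- setdiff(unique(as.vector(voxelData(object@annotation))), 0)
  if (length(labs) && any(!labs %in% object@nodeTable$label))
    msg <- c(msg, "every annotation label must appear in nodeTable")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "Phantom", function(object) {
  d <- dim(object@t1)
  cat(sprintf("Phantom: %d x %d x %d @ %.3g mm, %d node(s)\n",
              d[1], d[2], d[3], spacing(object@t1),
              nrow(object@nodeTable)))
  if (nrow(object@nodeTable))
    cat(sprintf("  node diameters: %.1f-%.1f mm\n",
                min(object@nodeTable$diameter_mm),
                max(object@nodeTable$diameter_mm)))
})

#' @describeIn Phantom the annotation label map as an ImageVolume.
#' @param object a \code{Phantom}.
#' @export
setGeneric("annotation", function(object) standardGeneric("annotation"))

#' @rdname Phantom
#' @export
setMethod("annotation", "Phantom", function(object) object@annotation)

#' Channel accessor for Phantom
#'
#' @param object a \linkS4class{Phantom}.
#' @param which \code{"t1"} (T1-like / VIBE-like) or \code{"t2star"}
#'   (T2*-like / MEDIC-like).
#' @return An \linkS4class{ImageVolume}.
#' @export
setGeneric("channel", function(object, which = "t1") standardGeneric("channel"))

#' @rdname channel
#' @export
setMethod("channel", "Phantom", function(object, which = "t1") {
  switch(match.arg(which, c("t1", "t2star")),
         t1 = object@t1, t2star = object@t2star)
})

#' FeatureStack: named per-voxel feature maps on a shared grid
#'
#' @slot maps 4D numeric array \code{[x, y, z, feature]}.
#' @slot featureNames character vector, one name per feature map.
#' @slot spacing isotropic voxel size in mm.
#' @slot scales Hessian smoothing scales used, in mm (may be empty).
#' @export
setClass("FeatureStack",
         representation(maps = "array", featureNames = "character",
                        spacing = "numeric", scales = "numeric"))

setValidity("FeatureStack", function(object) {
  msg <- NULL
  if (length(dim(object@maps)) != 4L)
    msg <- c(msg, "'maps' must be a 4D array [x, y, z, feature]")
  else if (dim(object@maps)[4] != length(object@featureNames))
    msg <- c(msg, "one name per feature map required")
  if (anyDuplicated(object@featureNames))
    msg <- c(msg, "feature names must be unique")
  if (any(!is.finite(object@maps)))
    msg <- c(msg, "feature maps must be finite")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn FeatureStack the ordered feature names.
#' @param object a \code{FeatureStack}.
#' @export
setGeneric("featureNames", function(object) standardGeneric("featureNames"))

#' @rdname FeatureStack
#' @export
setMethod("featureNames", "FeatureStack", function(object) object@featureNames)

#' @rdname voxelData
#' @export
setMethod("spacing", "FeatureStack", function(object) object@spacing)

#' Extract one feature map from a FeatureStack
#'
#' @param object a \linkS4class{FeatureStack}.
#' @param name feature name or integer position.
#' @return An \linkS4class{ImageVolume}.
#' @export
setGeneric("featureMap", function(object, name) standardGeneric("featureMap"))

#' @rdname featureMap
#' @export
setMethod("featureMap", "FeatureStack", function(object, name) {
  i <- if (is.character(name)) match(name, object@featureNames) else name
  if (is.na(i) || i < 1 || i > length(object@featureNames))
    stop("unknown feature: ", name)
  ImageVolume(object@maps[, , , i, drop = TRUE], object@spacing)
})

setMethod("show", "FeatureStack", function(object) {
  d <- dim(object@maps)
  cat(sprintf("FeatureStack: %d map(s) on %d x %d x %d @ %.3g mm\n",
              d[4], d[1], d[2], d[3], object@spacing))
  cat("  features:", paste(object@featureNames, collapse = ", "), "\n")
  if (length(object@scales))
    cat("  Hessian scales (mm):", paste(object@scales, collapse = ", "), "\n")
})

#' Feature matrix (voxels x features) from a FeatureStack
#'
#' @param object a \linkS4class{FeatureStack}.
#' @return Numeric matrix with one row per voxel (column-major voxel order)
#'   and one named column per feature.
#' @export
setGeneric("featureMatrix", function(object) standardGeneric("featureMatrix"))

#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "FeatureStack", function(object) {
  d <- dim(object@maps)
  m <- matrix(object@maps, nrow = prod(d[1:3]), ncol = d[4])
  colnames(m) <- object@featureNames
  m
})

#' BoostModel: GentleBoost ensemble of regression stumps
#'
#' @slot stumps data.frame with columns \code{feature_index} (1-based column
#'   in the feature matrix), \code{threshold}, \code{response_ge} (returned
#'   when feature >= threshold) and \code{response_lt}.
#' @slot featureNames feature-space provenance.
#' @slot nRounds number of boosting rounds requested.
#' @export
setClass("BoostModel",
         representation(stumps = "data.frame", featureNames = "character",
                        nRounds = "integer"))

setValidity("BoostModel", function(object) {
  msg <- NULL
  need <- c("feature_index", "threshold", "response_ge", "response_lt")
  if (!all(need %in% names(object@stumps)))
    msg <- c(msg, paste("stumps must have columns:", paste(need, collapse = ", ")))
  else {
    if (nrow(object@stumps) > object@nRounds)
      msg <- c(msg, "more stumps than rounds")
    if (length(object@featureNames) &&
        any(object@stumps$feature_index < 1 |
            object@stumps$feature_index > length(object@featureNames)))
      msg <- c(msg, "stump feature_index out of range")
    if (nrow(object@stumps) &&
        !all(is.finite(object@stumps$response_ge) &
             is.finite(object@stumps$response_lt)))
      msg <- c(msg, "stump responses must be finite")
  }
  if (is.null(msg)) TRUE else msg
})

#' @rdname FeatureStack
#' @export
setMethod("featureNames", "BoostModel", function(object) object@featureNames)

#' @describeIn BoostModel the fitted stumps as a data.frame.
#' @param object a \code{BoostModel}.
#' @export
setGeneric("stumps", function(object) standardGeneric("stumps"))

#' @rdname BoostModel
#' @export
setMethod("stumps", "BoostModel", function(object) object@stumps)

setMethod("show", "BoostModel", function(object) {
  cat(sprintf("BoostModel: %d regression stump(s) over %d feature(s)\n",
              nrow(object@stumps), length(object@featureNames)))
  if (nrow(object@stumps)) {
    used <- sort(table(object@featureNames[object@stumps$feature_index]),
                 decreasing = TRUE)
    cat("  most used:", paste(sprintf("%s (%d)", names(head(used, 3)),
                                      head(used, 3)), collapse = ", "), "\n")
  }
})

#' FROCCurve: free-response ROC operating points
#'
#' Operating points of a detection system at every distinct score threshold:
#' sensitivity (fraction of annotated nodes detected) against false
#' positives per node and per image.
#'
#' @slot thresholds descending score cutoffs.
#' @slot sensitivity fraction of annotated nodes detected at each cutoff.
#' @slot fpPerNode false positives divided by the total number of nodes.
#' @slot fpPerImage false positives divided by the number of images.
#' @slot nNodes,nImages normalizers.
#' @export
setClass("FROCCurve",
         representation(thresholds = "numeric", sensitivity = "numeric",
                        fpPerNode = "numeric", fpPerImage = "numeric",
                        nNodes = "integer", nImages = "integer"))

setValidity("FROCCurve", function(object) {
  msg <- NULL
  n <- length(object@thresholds)
  if (length(object@sensitivity) != n || length(object@fpPerNode) != n ||
      length(object@fpPerImage) != n)
    msg <- c(msg, "all operating-point vectors must have equal length")
  if (any(object@sensitivity < 0 | object@sensitivity > 1))
    msg <- c(msg, "sensitivity must lie in [0, 1]")
  if (n > 1 && is.unsorted(object@sensitivity))
    msg <- c(msg, "sensitivity must be non-decreasing as the threshold drops")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "FROCCurve", function(object) {
  cat(sprintf("FROCCurve: %d operating point(s), %d node(s), %d image(s)\n",
              length(object@thresholds), object@nNodes, object@nImages))
  if (length(object@thresholds))
    cat(sprintf("  max sensitivity %.3f at %.2f FP/image\n",
                max(object@sensitivity), max(object@fpPerImage)))
})

#' Operating points of a FROCCurve as a data.frame
#'
#' @param object a \linkS4class{FROCCurve}.
#' @return data.frame with columns threshold, sensitivity, fp_per_node,
#'   fp_per_image.
#' @export
setGeneric("operatingPoints",
           function(object) standardGeneric("operatingPoints"))

#' @rdname operatingPoints
#' @export
setMethod("operatingPoints", "FROCCurve", function(object) {
  data.frame(threshold = object@thresholds,
             sensitivity = object@sensitivity,
             fp_per_node = object@fpPerNode,
             fp_per_image = object@fpPerImage)
})

#' MVCNNModel: multi-view convolutional network
#'
#' Weights and architecture of the multi-view CNN used for false-positive
#' reduction. One conv-pool-conv-pool-conv branch per view (weights not
#' shared between branches), feature concatenation, a hidden fully-connected
#' ReLU layer with dropout, and a 2-way softmax output.
#'
#' @slot spec list: n_views, input_size, conv_channels, fc_units, kernel.
#' @slot weights nested list of weight matrices (per-branch W1/b1/W2/b2/W3/b3
#'   plus fc1W/fc1b/fc2W/fc2b).
#' @export
setClass("MVCNNModel", representation(spec = "list", weights = "list"))

setMethod("show", "MVCNNModel", function(object) {
  s <- object@spec
  np <- sum(vapply(rapply(object@weights, length, how = "unlist"),
                   identity, numeric(1)))
  cat(sprintf("MVCNNModel: %d-view, input %dx%d, conv %s, FC %d, %s parameters\n",
              s$n_views, s$input_size, s$input_size,
              paste(s$conv_channels, collapse = "/"), s$fc_units,
              format(np, big.mark = ",")))
})
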