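# Standard-format I/O: NIfTI volumes, candidate CSVs, boost-model JSON,
# YAML configuration.

#' Read a 3D volume from NIfTI
#'
#' @param path a .nii or .nii.gz file with isotropic voxels.
#' @return An \linkS4class{ImageVolume}.
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3 || max(abs(pd - pd[1])) > 1e-6 * pd[1])
    stop("unsupported input: non-isotropic voxels in ", path)
  arr <- array(as.numeric(img), dim(img))
  ImageVolume(arr, pd[1])
}

#' Write a volume (or integer label map) to NIfTI
#'
#' @param volume an \linkS4class{ImageVolume}.
#' @param path output .nii or .nii.gz path.
#' @param datatype passed to \code{RNifti::writeNifti}; label maps should
#'   use \code{"int16"}.
#' @return the path, invisibly.
#' @export
writeVolume <- function(volume, path, datatype = "auto") {
  stopifnot(is(volume, "ImageVolume"))
  img <- RNifti::asNifti(voxelData(volume))
  RNifti::pixdim(img) <- rep(spacing(volume), 3)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write / read a candidate table as CSV
#'
#' Columns: index_x, index_y, index_z (1-based voxel indices),
#' pos_mm_x/y/z, likelihood, and when present cnn_probability and
#' node_label.
#'
#' @param candidates data.frame of candidates.
#' @param path CSV path.
#' @return \code{writeCandidates}: the path, invisibly;
#'   \code{readCandidates}: a data.frame.
#' @export
writeCandidates <- function(candidates, path) {
  write.csv(candidates, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCandidates
#' @export
readCandidates <- function(path) {
  read.csv(path)
}

#' Serialize / load a BoostModel as JSON
#'
#' @param model a \linkS4class{BoostModel}.
#' @param path JSON path.
#' @return \code{writeBoostModel}: the path, invisibly;
#'   \code{readBoostModel}: a \linkS4class{BoostModel}.
#' @export
writeBoostModel <- function(model, path) {
  stopifnot(is(model, "BoostModel"))
  jsonlite::write_json(list(feature_names = featureNames(model),
                            n_rounds = model@nRounds,
                            stumps = stumps(model)),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeBoostModel
#' @export
readBoostModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("BoostModel", stumps = as.data.frame(x$stumps),
      featureNames = as.character(x$feature_names),
      nRounds = as.integer(x$n_rounds))
}

#' Write an FROC curve (with optional bootstrap bands) as CSV
#'
#' @param curve a \linkS4class{FROCCurve}.
#' @param path CSV path.
#' @param bands optional band data.frame from \code{\link{bootstrapFROC}}.
#' @return the path, invisibly.
#' @export
writeFROCCurve <- function(curve, path, bands = NULL) {
  df <- operatingPoints(curve)
  write.csv(df, path, row.names = FALSE)
  if (!is.null(bands))
    write.csv(bands, sub("(\\.csv)?$", "_bands.csv", path, perl = TRUE),
              row.names = FALSE)
  invisible(path)
}

#' Write / read a candidate patch array with an ordering sidecar
#'
#' Stores the stacked patch array \code{[size, size, n_views, n]} as a 4D
#' NIfTI plus a JSON sidecar documenting the dimension order, the view ids
#' and the sampling step, so the extraction geometry is reconstructible.
#'
#' @param patches 4D array from \code{\link{candidatePatchArray}}.
#' @param path output .nii.gz path (the sidecar gets extension .json).
#' @param view_ids view identifiers in patch order.
#' @param step_mm in-plane sampling step recorded in the sidecar.
#' @return \code{writePatchArray}: the path, invisibly;
#'   \code{readPatchArray}: a list with \code{patches} and \code{sidecar}.
#' @export
writePatchArray <- function(patches, path, view_ids = NULL, step_mm = 0.8) {
  stopifnot(length(dim(patches)) == 4)
  if (is.null(view_ids)) view_ids <- seq_len(dim(patches)[3]) - 1L
  img <- RNifti::asNifti(patches)
  RNifti::writeNifti(img, path)
  sidecar <- list(dim_order = c("patch_i", "patch_j", "view", "candidate"),
                  size = dim(patches)[1], view_ids = view_ids,
                  n_candidates = dim(patches)[4], step_mm = step_mm)
  jsonlite::write_json(sidecar, sub("(\\.nii(\\.gz)?)?$", ".json", path,
                                    perl = TRUE),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePatchArray
#' @export
readPatchArray <- function(path) {
  img <- RNifti::readNifti(path)
  sidecar <- jsonlite::read_json(sub("(\\.nii(\\.gz)?)?$", ".json", path,
                                     perl = TRUE),
                                 simplifyVector = TRUE)
  list(patches = array(as.numeric(img), dim(img)), sidecar = sidecar)
}

#' Serialize / load a multi-view network checkpoint
#'
#' Weights go to an RDS checkpoint; the architecture (and optionally the
#' training configuration and history) goes to a JSON sidecar next to it.
#'
#' @param model an \linkS4class{MVCNNModel}.
#' @param path checkpoint path (e.g. \code{model.rds}).
#' @param train_config optional \code{\link{trainConfig}} to record.
#' @param history optional training history data.frame to record.
#' @return \code{writeMVCNNModel}: the path, invisibly;
#'   \code{readMVCNNModel}: an \linkS4class{MVCNNModel}.
#' @export
writeMVCNNModel <- function(model, path, train_config = NULL,
                            history = NULL) {
  stopifnot(is(model, "MVCNNModel"))
  saveRDS(model@weights, path)
  sidecar <- list(spec = model@spec)
  if (!is.null(train_config)) sidecar$train_config <- unclass(train_config)
  if (!is.null(history)) sidecar$history <- history
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname writeMVCNNModel
#' @export
readMVCNNModel <- function(path) {
  weights <- readRDS(path)
  sidecar <- jsonlite::read_json(paste0(path, ".json"),
                                 simplifyVector = TRUE)
  spec <- sidecar$spec
  spec$conv_channels <- as.integer(spec$conv_channels)
  new("MVCNNModel", spec = spec, weights = weights)
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults from
#' \code{\link{pipelineConfig}}; everything else keeps the reference
#' defaults.
#'
#' @param path YAML file.
#' @return a pipeline configuration list.
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  base <- pipelineConfig()
  modifyList(base, user)
}
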