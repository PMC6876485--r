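# Stage-1 voxel features: normalized channel intensities, multi-scale
# Hessian shape measures (blobness / vesselness / sheetness) and simple
# positional maps (signed landmark distances + normalized coordinates).

# sampled 1D Gaussian kernel (sum-normalized) and its derivative kernels,
# with x in mm so that derivatives are per-mm
.gaussKernel1D <- function(sigma_mm, spacing_mm, order = 0L) {
  r <- max(1L, ceiling(3 * sigma_mm / spacing_mm))
  x <- (-r:r) * spacing_mm
  g <- exp(-x^2 / (2 * sigma_mm^2))
  g <- g / sum(g)
  switch(as.character(order),
         "0" = g,
         "1" = -x / sigma_mm^2 * g,
         "2" = (x^2 - sigma_mm^2) / sigma_mm^4 * g,
         stop("unsupported derivative order"))
}

#' Normalize a volume by its mean and standard deviation
#'
#' Scales intensities to \eqn{(I - \mu)/\sigma} using the per-volume mean
#' \eqn{\mu} and population standard deviation \eqn{\sigma}, so each channel
#' enters the classifier on a common scale.
#'
#' @param volume an \linkS4class{ImageVolume} with more than one voxel.
#' @return An \linkS4class{ImageVolume} with mean 0 and SD 1.
#' @examples
#' v <- ImageVolume(array(rnorm(512, 100, 10), c(8, 8, 8)))
#' z <- normalizeIntensity(v)
#' c(mean(voxelData(z)), sd(voxelData(z)))
#' @export
normalizeIntensity <- function(volume) {
  stopifnot(is(volume, "ImageVolume"))
  x <- voxelData(volume)
  if (length(x) < 2) stop("volume must have more than one voxel")
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))  # population SD
  if (sigma == 0)
    stop("degenerate input: constant volume (sigma = 0) cannot be normalized")
  ImageVolume((x - mu) / sigma, spacing(volume))
}

# Hessian of a volume at one Gaussian scale; returns the six unique
# components, gamma-normalized by sigma^2 (second-order scale normalization)
.hessianAtScale <- function(x, dims, spacing, sigma) {
  g0 <- .gaussKernel1D(sigma, spacing, 0L)
  g1 <- .gaussKernel1D(sigma, spacing, 1L)
  g2 <- .gaussKernel1D(sigma, spacing, 2L)
  s2 <- sigma^2
  list(xx = s2 * .sepConvolve3D(x, dims, g2, g0, g0),
       yy = s2 * .sepConvolve3D(x, dims, g0, g2, g0),
       zz = s2 * .sepConvolve3D(x, dims, g0, g0, g2),
       xy = s2 * .sepConvolve3D(x, dims, g1, g1, g0),
       xz = s2 * .sepConvolve3D(x, dims, g1, g0, g1),
       yz = s2 * .sepConvolve3D(x, dims, g0, g1, g1))
}

#' Hessian-based blobness, vesselness and sheetness maps
#'
#' Computes Gaussian-smoothed Hessian eigenvalues
#' \eqn{|\lambda_1| \le |\lambda_2| \le |\lambda_3|} at each voxel and scale,
#' and derives three bounded shape measures in the Frangi style from the
#' eigenvalue ratios \eqn{R_A = |\lambda_2|/|\lambda_3|},
#' \eqn{R_B = |\lambda_1|/\sqrt{|\lambda_2 \lambda_3|}} and the second-order
#' structureness \eqn{S} (Frobenius norm of the Hessian):
#' \itemize{
#'   \item blobness: high where all three eigenvalues are negative (bright
#'     structure) and of similar magnitude;
#'   \item vesselness: high where \eqn{|\lambda_1| \ll |\lambda_2| \approx
#'     |\lambda_3|} with \eqn{\lambda_2, \lambda_3 < 0};
#'   \item sheetness: high where \eqn{|\lambda_1| \approx |\lambda_2| \ll
#'     |\lambda_3|} with \eqn{\lambda_3 < 0}.
#' }
#' Responses are aggregated over scales by the voxelwise maximum, and all
#' maps lie in \eqn{[0, 1]}. The structureness cutoff \code{c} adapts per
#' volume and scale to half the maximum Frobenius norm of the Hessian.
#'
#' @param volume an \linkS4class{ImageVolume}; bright structures are assumed
#'   (set \code{polarity = "dark"} to negate first).
#' @param scales_mm Gaussian smoothing scales in mm; the defaults bracket
#'   the 3-10 mm node diameter range.
#' @param alpha,beta Frangi ratio sensitivities.
#' @param polarity \code{"bright"} or \code{"dark"}.
#' @return A \linkS4class{FeatureStack} with maps \code{blobness},
#'   \code{vesselness}, \code{sheetness}.
#' @export
hessianShapeFeatures <- function(volume, scales_mm = c(1.6, 2.4, 3.2),
                                 alpha = 0.5, beta = 0.5,
                                 polarity = c("bright", "dark")) {
  stopifnot(is(volume, "ImageVolume"))
  if (length(scales_mm) == 0)
    stop("config error: at least one Hessian scale is required")
  if (any(scales_mm <= 0)) stop("config error: scales must be positive")
  polarity <- match.arg(polarity)
  x <- voxelData(volume)
  if (polarity == "dark") x <- -x
  dims <- dim(x)
  s <- spacing(volume)
  n <- prod(dims)
  blob <- vess <- sheet <- numeric(n)
  for (sigma in scales_mm) {
    H <- .hessianAtScale(x, dims, s, sigma)
    ev <- .eigSym3Field(H$xx, H$yy, H$zz, H$xy, H$xz, H$yz)
    a1 <- abs(ev$l1); a2 <- abs(ev$l2); a3 <- abs(ev$l3)
    S2 <- a1^2 + a2^2 + a3^2
    cmax <- sqrt(max(S2))
    if (cmax == 0) next  # featureless volume at this scale
    c2 <- (cmax / 2)^2
    eps <- 1e-12
    RA2 <- (a2 / pmax(a3, eps))^2
    RB2 <- a1^2 / pmax(a2 * a3, eps)
    fA <- 1 - exp(-RA2 / (2 * alpha^2))   # ~1 when |l2| ~ |l3|
    fB <- exp(-RB2 / (2 * beta^2))        # ~1 when |l1| small
    fS <- 1 - exp(-S2 / (2 * c2))         # structure present
    bright23 <- ev$l2 < 0 & ev$l3 < 0
    bright123 <- bright23 & ev$l1 < 0
    vess <- pmax(vess, ifelse(bright23, fA * fB * fS, 0))
    blob <- pmax(blob, ifelse(bright123, fA * (1 - fB) * fS, 0))
    sheet <- pmax(sheet, ifelse(ev$l3 < 0, (1 - fA) * fB * fS, 0))
  }
  maps <- array(c(blob, vess, sheet), c(dims, 3L))
  new("FeatureStack", maps = maps,
      featureNames = c("blobness", "vesselness", "sheetness"),
      spacing = s, scales = as.numeric(scales_mm))
}

#' Positional feature maps
#'
#' One signed Euclidean distance map (mm) per landmark mask, negative inside
#' the landmark, plus three normalized coordinate maps scaling each axis
#' position to \eqn{[0, 1]} over the grid. These stand in for atlas-derived
#' positional features: on synthetic phantoms there is no pelvic anatomy to
#' register, so position is encoded directly.
#'
#' @param volume an \linkS4class{ImageVolume} defining the grid.
#' @param landmarks named list of logical 3D arrays (or 0/1 arrays) on the
#'   same grid.
#' @return A \linkS4class{FeatureStack} with maps \code{pos_x}, \code{pos_y},
#'   \code{pos_z} and one \code{dist_<name>} per landmark.
#' @export
positionalFeatures <- function(volume, landmarks = list()) {
  stopifnot(is(volume, "ImageVolume"))
  dims <- dim(volume)
  s <- spacing(volume)
  coord <- function(axis) {
    n <- dims[axis]
    v <- if (n > 1) (seq_len(n) - 1) / (n - 1) else rep(0, n)
    perm <- array(0, dims)
    if (axis == 1) perm[] <- rep(v, times = dims[2] * dims[3])
    if (axis == 2) perm[] <- rep(rep(v, each = dims[1]), times = dims[3])
    if (axis == 3) perm[] <- rep(v, each = dims[1] * dims[2])
    perm
  }
  maps <- list(pos_x = coord(1), pos_y = coord(2), pos_z = coord(3))
  if (length(landmarks)) {
    nms <- names(landmarks)
    if (is.null(nms)) nms <- paste0("landmark", seq_along(landmarks))
    for (i in seq_along(landmarks)) {
      m <- landmarks[[i]]
      if (!identical(dim(m), dims))
        stop("shape error: landmark '", nms[i], "' is not on the volume grid")
      m <- array(as.logical(m), dims)
      if (!any(m)) stop("landmark '", nms[i], "' is empty")
      d_out <- sqrt(.edtSquared3D(m, dims)) * s
      d_in <- sqrt(.edtSquared3D(!m, dims)) * s
      maps[[paste0("dist_", nms[i])]] <- d_out - d_in
    }
  }
  arr <- array(unlist(maps, use.names = FALSE), c(dims, length(maps)))
  new("FeatureStack", maps = arr, featureNames = names(maps),
      spacing = s, scales = numeric(0))
}

#' Assemble the stage-1 feature stack for a phantom or channel pair
#'
#' Combines the normalized intensity of each channel, Hessian shape features
#' computed on the (normalized) T1-like channel, and positional features,
#' into a single stack feeding the voxel classifier.
#'
#' @param phantom a \linkS4class{Phantom}, or a named list with elements
#'   \code{t1} and (optionally) \code{t2star} of \linkS4class{ImageVolume}s.
#' @param scales_mm Hessian scales in mm.
#' @param landmarks optional landmark masks for
#'   \code{\link{positionalFeatures}}.
#' @param hessian_channel channel used for the shape features.
#' @return A \linkS4class{FeatureStack}.
#' @export
buildFeatureStack <- function(phantom, scales_mm = c(1.6, 2.4, 3.2),
                              landmarks = list(),
                              hessian_channel = c("t1", "t2star")) {
  hessian_channel <- match.arg(hessian_channel)
  if (is(phantom, "Phantom"))
    vols <- list(t1 = channel(phantom, "t1"),
                 t2star = channel(phantom, "t2star"))
  else vols <- phantom
  stopifnot(is(vols$t1, "ImageVolume"))
  norm <- lapply(vols, normalizeIntensity)
  hess <- hessianShapeFeatures(norm[[hessian_channel]], scales_mm)
  pos <- positionalFeatures(vols$t1, landmarks)
  dims <- dim(vols$t1)
  mats <- c(lapply(norm, voxelData),
            lapply(seq_along(featureNames(hess)),
                   function(i) hess@maps[, , , i]),
            lapply(seq_along(featureNames(pos)),
                   function(i) pos@maps[, , , i]))
  nms <- c(paste0(names(norm), "_intensity"), featureNames(hess),
           featureNames(pos))
  arr <- array(unlist(mats, use.names = FALSE), c(dims, length(mats)))
  new("FeatureStack", maps = arr, featureNames = nms,
      spacing = spacing(vols$t1), scales = as.numeric(scales_mm))
}
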