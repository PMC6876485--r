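#' Configuration for the synthetic MRL phantom generator
#'
#' The phantom emulates a 0.8 mm isotropic dual-channel pelvic MRL study:
#' bright nodular structures (lymph nodes, ellipsoids of 3-10 mm diameter),
#' curved tubular structures (vessels), thin sheet-like structures, and
#' additive Gaussian noise on two channels sharing the geometry but with
#' independent contrasts. Nodes above 10 mm are rejected because 10 mm is
#' the maximum size of non-enlarged lymph nodes targeted by the detector's
#' spherical search window.
#'
#' @param grid_shape integer(3), voxels per axis.
#' @param spacing_mm isotropic voxel size in mm.
#' @param n_nodes,n_vessels,n_sheets structure counts (>= 0).
#' @param node_diameter_range_mm (min, max) node diameter in mm; max <= 10.
#' @param vessel_radius_range_mm (min, max) vessel tube radius in mm.
#' @param sheet_thickness_mm slab thickness in mm.
#' @param node_contrast,vessel_contrast,sheet_contrast length-2 numeric:
#'   additive intensity above background for (T1-like, T2*-like) channels.
#' @param background_level length-2 numeric baseline intensity per channel.
#' @param noise_sd additive Gaussian noise standard deviation (both channels).
#' @param hypointense_nodes_t2star if TRUE, nodes are darker than background
#'   in the T2*-like channel (USPIO-uptake-like appearance); off by default.
#' @param margin_mm minimum distance from any structure surface to the grid
#'   boundary; patches sampled near borders are zero-padded downstream, so
#'   the margin only needs to keep structures fully inside the grid.
#' @param smooth_sigma_mm small Gaussian blur applied to the noiseless
#'   structure image to mimic partial-volume softening (0 disables).
#' @param seed RNG seed; a fixed seed reproduces the phantom bit-exactly.
#' @return An object of class \code{PhantomConfig} (a validated list).
#' @examples
#' cfg <- phantomConfig(grid_shape = c(48, 48, 48), n_nodes = 2, seed = 7)
#' @export
phantomConfig <- function(grid_shape = c(64L, 64L, 64L),
                          spacing_mm = 0.8,
                          n_nodes = 4L,
                          node_diameter_range_mm = c(3, 10),
                          n_vessels = 3L,
                          vessel_radius_range_mm = c(1, 2.5),
                          n_sheets = 1L,
                          sheet_thickness_mm = 1.6,
                          node_contrast = c(80, 50),
                          vessel_contrast = c(60, 70),
                          sheet_contrast = c(40, 40),
                          background_level = c(100, 100),
                          noise_sd = 10,
                          hypointense_nodes_t2star = FALSE,
                          margin_mm = 6,
                          smooth_sigma_mm = 0.4,
                          seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8),
            length(spacing_mm) == 1L, spacing_mm > 0,
            n_nodes >= 0, n_vessels >= 0, n_sheets >= 0,
            length(node_diameter_range_mm) == 2L,
            node_diameter_range_mm[1] > 0,
            diff(node_diameter_range_mm) >= 0,
            length(vessel_radius_range_mm) == 2L,
            vessel_radius_range_mm[1] > 0,
            length(node_contrast) == 2L, length(vessel_contrast) == 2L,
            length(sheet_contrast) == 2L, length(background_level) == 2L,
            noise_sd >= 0, margin_mm >= 0, smooth_sigma_mm >= 0)
  if (node_diameter_range_mm[2] > 10)
    stop("node diameters above 10 mm are outside the detector's design range")
  cfg <- list(grid_shape = as.integer(grid_shape), spacing_mm = spacing_mm,
              n_nodes = as.integer(n_nodes),
              node_diameter_range_mm = node_diameter_range_mm,
              n_vessels = as.integer(n_vessels),
              vessel_radius_range_mm = vessel_radius_range_mm,
              n_sheets = as.integer(n_sheets),
              sheet_thickness_mm = sheet_thickness_mm,
              node_contrast = node_contrast,
              vessel_contrast = vessel_contrast,
              sheet_contrast = sheet_contrast,
              background_level = background_level,
              noise_sd = noise_sd,
              hypointense_nodes_t2star = isTRUE(hypointense_nodes_t2star),
              margin_mm = margin_mm, smooth_sigma_mm = smooth_sigma_mm,
              seed = as.integer(seed))
  class(cfg) <- "PhantomConfig"
  cfg
}

# voxel-center world coordinates (mm) of all grid voxels along one axis
.axisCenters <- function(n, spacing) (seq_len(n) - 0.5) * spacing

# random 3D rotation matrix (uniform via QR of Gaussian matrix)
.randomRotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# voxelize an ellipsoid: center (mm), semi-axes (mm), rotation R
.ellipsoidMask <- function(dims, spacing, center, semi, R) {
  r <- max(semi) + spacing
  lo <- pmax(1L, floor(center / spacing - r / spacing))
  hi <- pmin(dims, ceiling(center / spacing + r / spacing))
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  g <- as.matrix(expand.grid(x = .axisCenters(dims[1], spacing)[ix],
                             y = .axisCenters(dims[2], spacing)[iy],
                             z = .axisCenters(dims[3], spacing)[iz]))
  d <- sweep(g, 2, center) %*% t(R)
  inside <- (d[, 1] / semi[1])^2 + (d[, 2] / semi[2])^2 +
    (d[, 3] / semi[3])^2 <= 1
  idx <- as.matrix(expand.grid(ix, iy, iz))[inside, , drop = FALSE]
  idx
}

#' Generate a synthetic dual-channel MRL phantom
#'
#' Places non-overlapping ellipsoidal nodes, curved polyline-swept tubes
#' (vessels) and thin slabs (sheets) in a 3D grid, renders both channels
#' with the configured contrasts, applies a mild partial-volume blur and
#' additive Gaussian noise, and returns the ground-truth label map in which
#' node \code{k} carries label \code{k}. Output is deterministic for a
#' fixed \code{config$seed}.
#'
#' Vessels are swept along polylines with mild random curvature so that they
#' intersect sampling planes both longitudinally and transversally; the
#' tubular-versus-nodular ambiguity they create is the main source of
#' stage-1 false positives that the multi-view CNN stage must resolve.
#'
#' @param config a \code{\link{phantomConfig}}.
#' @return A \linkS4class{Phantom}.
#' @examples
#' ph <- generatePhantom(phantomConfig(grid_shape = c(48, 48, 48),
#'                                     n_nodes = 2, n_vessels = 1,
#'                                     n_sheets = 0, seed = 3))
#' ph
#' @export
generatePhantom <- function(config) {
  stopifnot(inherits(config, "PhantomConfig"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  dims <- config$grid_shape
  s <- config$spacing_mm
  ext <- dims * s
  margin <- config$margin_mm
  max_retry <- 200L

  ann <- array(0L, dims)
  struct1 <- array(0, dims)  # T1-like structure contrast
  struct2 <- array(0, dims)

  # ---- nodes: random ellipsoids, mutually non-overlapping ----
  node_centers <- matrix(NA_real_, config$n_nodes, 3)
  node_radius <- numeric(config$n_nodes)
  nodeTable <- data.frame(label = integer(0), diameter_mm = numeric(0),
                          center_x_mm = numeric(0), center_y_mm = numeric(0),
                          center_z_mm = numeric(0))
  for (k in seq_len(config$n_nodes)) {
    d <- runif(1, config$node_diameter_range_mm[1],
               config$node_diameter_range_mm[2])
    rmax <- d / 2
    if (any(ext - 2 * (margin + rmax) <= 0))
      stop("phantom placement error: grid too small for a ", round(d, 1),
           " mm node at margin ", margin, " mm")
    placed <- FALSE
    for (try in seq_len(max_retry)) {
      ctr <- runif(3, margin + rmax, ext - margin - rmax)
      ok <- k == 1L ||
        all(sqrt(rowSums(sweep(node_centers[seq_len(k - 1), , drop = FALSE],
                               2, ctr)^2)) >
              node_radius[seq_len(k - 1)] + rmax + 2)
      if (ok) { placed <- TRUE; break }
    }
    if (!placed)
      stop("phantom placement error: could not place node ", k,
           " without overlap; enlarge the grid or reduce n_nodes")
    semi <- rmax * c(1, runif(1, 0.75, 1), runif(1, 0.75, 1))
    R <- .randomRotation()
    idx <- .ellipsoidMask(dims, s, ctr, semi, R)
    ann[idx] <- k
    struct1[idx] <- pmax(struct1[idx], config$node_contrast[1])
    t2c <- if (config$hypointense_nodes_t2star) -abs(config$node_contrast[2]) else config$node_contrast[2]
    struct2[idx] <- if (t2c >= 0) pmax(struct2[idx], t2c) else t2c
    node_centers[k, ] <- ctr
    node_radius[k] <- rmax
    nodeTable <- rbind(nodeTable,
                       data.frame(label = k, diameter_mm = d,
                                  center_x_mm = ctr[1], center_y_mm = ctr[2],
                                  center_z_mm = ctr[3]))
  }

  # ---- vessels: polyline-swept curved tubes avoiding the nodes ----
  vs_mask <- array(FALSE, dims)
  for (k in seq_len(config$n_vessels)) {
    r <- runif(1, config$vessel_radius_range_mm[1],
               config$vessel_radius_range_mm[2])
    placed <- FALSE
    for (try in seq_len(max_retry)) {
      start <- runif(3, margin + r, ext - margin - r)
      dirv <- rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
      step <- 1.5  # mm between polyline vertices
      pts <- list(start)
      p <- start
      repeat {
        dirv <- dirv + rnorm(3, sd = 0.12)  # mild curvature
        dirv <- dirv / sqrt(sum(dirv^2))
        p <- p + step * dirv
        if (any(p < margin + r) || any(p > ext - margin - r)) break
        pts[[length(pts) + 1L]] <- p
        if (length(pts) > 200L) break
      }
      if (length(pts) < 8L) next  # too short to look like a vessel
      P <- do.call(rbind, pts)
      if (config$n_nodes > 0) {
        clear <- TRUE
        for (j in seq_len(config$n_nodes)) {
          dmin <- min(sqrt(rowSums(sweep(P, 2, node_centers[j, ])^2)))
          if (dmin < node_radius[j] + r + 1.5) { clear <- FALSE; break }
        }
        if (!clear) next
      }
      placed <- TRUE
      break
    }
    if (!placed)
      stop("phantom placement error: could not route vessel ", k)
    # densify the centerline and mark its voxels, then dilate to the radius
    seg <- diff(P)
    dense <- do.call(rbind, lapply(seq_len(nrow(seg)), function(i) {
      n <- max(2L, ceiling(sqrt(sum(seg[i, ]^2)) / (0.4 * s)))
      t <- seq(0, 1, length.out = n)
      cbind(P[i, 1] + t * seg[i, 1], P[i, 2] + t * seg[i, 2],
            P[i, 3] + t * seg[i, 3])
    }))
    ci <- unique(pmin(pmax(round(dense / s + 0.5), 1),
                      matrix(dims, nrow(dense), 3, byrow = TRUE)))
    ci <- matrix(as.integer(ci), ncol = 3)
    cl <- array(FALSE, dims)
    cl[ci] <- TRUE
    d2 <- .edtSquared3D(cl, dims)
    tube <- d2 * s * s <= r * r
    vs_mask <- vs_mask | tube
  }
  if (any(vs_mask)) {
    struct1[vs_mask] <- pmax(struct1[vs_mask], config$vessel_contrast[1])
    struct2[vs_mask] <- pmax(struct2[vs_mask], config$vessel_contrast[2])
  }

  # ---- sheets: thin bounded slabs avoiding the nodes ----
  for (k in seq_len(config$n_sheets)) {
    placed <- FALSE
    for (try in seq_len(max_retry)) {
      nrm <- rnorm(3); nrm <- nrm / sqrt(sum(nrm^2))
      p0 <- runif(3, margin, ext - margin)
      if (config$n_nodes > 0) {
        dplane <- abs(as.vector(sweep(node_centers, 2, p0) %*% nrm))
        # keep the slab away from nodes unless laterally far away
        lat <- sqrt(pmax(rowSums(sweep(node_centers, 2, p0)^2) - dplane^2, 0))
        if (any(dplane < node_radius + config$sheet_thickness_mm / 2 + 1.5 &
                lat < 18)) next
      }
      placed <- TRUE
      break
    }
    if (!placed)
      stop("phantom placement error: could not place sheet ", k)
    cx <- .axisCenters(dims[1], s); cy <- .axisCenters(dims[2], s)
    cz <- .axisCenters(dims[3], s)
    # signed distance to the plane, vectorized over the full grid
    gx <- array(rep(cx, times = dims[2] * dims[3]), dims)
    gy <- array(rep(rep(cy, each = dims[1]), times = dims[3]), dims)
    gz <- array(rep(cz, each = dims[1] * dims[2]), dims)
    dplane <- (gx - p0[1]) * nrm[1] + (gy - p0[2]) * nrm[2] +
      (gz - p0[3]) * nrm[3]
    lat2 <- (gx - p0[1])^2 + (gy - p0[2])^2 + (gz - p0[3])^2 - dplane^2
    slab <- abs(dplane) <= config$sheet_thickness_mm / 2 & lat2 <= 15^2
    struct1[slab] <- pmax(struct1[slab], config$sheet_contrast[1])
    struct2[slab] <- pmax(struct2[slab], config$sheet_contrast[2])
  }

  # ---- render channels: blur the structures, add background and noise ----
  render <- function(structure, level) {
    if (config$smooth_sigma_mm > 0) {
      kern <- .gaussKernel1D(config$smooth_sigma_mm, s)
      structure <- .sepConvolve3D(structure, dims, kern, kern, kern)
    }
    structure + level + array(rnorm(prod(dims), sd = config$noise_sd), dims)
  }
  t1 <- render(struct1, config$background_level[1])
  t2 <- render(struct2, config$background_level[2])

  new("Phantom",
      t1 = ImageVolume(t1, s), t2star = ImageVolume(t2, s),
      annotation = ImageVolume(ann, s), nodeTable = nodeTable,
      config = config)
}

#' Per-node centers of gravity and volumes from an annotation map
#'
#' @param annotation \linkS4class{ImageVolume} whose voxels carry integer
#'   node labels (0 = background), or a \linkS4class{Phantom}.
#' @param spacing_mm voxel size; taken from the volume when omitted.
#' @return data.frame with one row per label: \code{label},
#'   \code{n_voxels}, \code{volume_ml} (\code{n_voxels * spacing^3 / 1000})
#'   and the unweighted center of gravity of member voxel centers
#'   \code{cog_x_mm}, \code{cog_y_mm}, \code{cog_z_mm}.
#' @examples
#' a <- array(0L, c(20, 20, 20)); a[10, 10, 10] <- 1L
#' nodeProperties(ImageVolume(a, 0.8))   # center (7.6, 7.6, 7.6) mm
#' @export
nodeProperties <- function(annotation, spacing_mm = NULL) {
  if (is(annotation, "Phantom")) annotation <- annotation(annotation)
  stopifnot(is(annotation, "ImageVolume"))
  if (is.null(spacing_mm)) spacing_mm <- spacing(annotation)
  a <- voxelData(annotation)
  labs <- sort(setdiff(unique(as.vector(a)), 0))
  if (!length(labs))
    return(data.frame(label = integer(0), n_voxels = integer(0),
                      volume_ml = numeric(0), cog_x_mm = numeric(0),
                      cog_y_mm = numeric(0), cog_z_mm = numeric(0)))
  idx <- which(a != 0, arr.ind = TRUE)
  lab <- a[idx]
  out <- do.call(rbind, lapply(labs, function(l) {
    m <- idx[lab == l, , drop = FALSE]
    ctr <- (colMeans(m) - 0.5) * spacing_mm
    data.frame(label = l, n_voxels = nrow(m),
               volume_ml = nrow(m) * spacing_mm^3 / 1000,
               cog_x_mm = ctr[1], cog_y_mm = ctr[2], cog_z_mm = ctr[3])
  }))
  rownames(out) <- NULL
  out
}
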