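# Multi-view 2D patch sampling on the symmetry planes of a cube enclosing
# each candidate: 3 axis-aligned planes plus 6 edge-diagonal planes.

#' Enumerate the nine view bases
#'
#' The nine sampling planes are the symmetry planes of a cube centered on
#' the candidate. Views 0-2 are the axis-aligned planes (view 0 is the
#' original acquisition plane, mapped to the volume's first two axes);
#' views 3-8 run diagonally from one cube edge to the opposite edge, with
#' in-plane axis \code{u} a face diagonal and \code{v} the remaining
#' coordinate axis. The 1-view subset is \{0\}, the 3-view subset \{0, 1, 2\},
#' and the 9-view subset all of them, in this fixed order.
#'
#' @return list of 9 bases; each has \code{view_id} (0-8), unit in-plane
#'   axes \code{u}, \code{v}, and \code{normal = u x v}.
#' @examples
#' b <- enumerateViewBases()
#' sapply(b, function(x) sum(x$u * x$v))  # all orthogonal
#' @export
enumerateViewBases <- function() {
  e1 <- c(1, 0, 0); e2 <- c(0, 1, 0); e3 <- c(0, 0, 1)
  r2 <- 1 / sqrt(2)
  defs <- list(
    list(u = e1, v = e2),                    # 0: original image plane
    list(u = e2, v = e3),                    # 1
    list(u = e3, v = e1),                    # 2
    list(u = c(1, 1, 0) * r2, v = e3),       # 3
    list(u = c(1, -1, 0) * r2, v = e3),      # 4
    list(u = c(1, 0, 1) * r2, v = e2),       # 5
    list(u = c(1, 0, -1) * r2, v = e2),      # 6
    list(u = c(0, 1, 1) * r2, v = e1),       # 7
    list(u = c(0, 1, -1) * r2, v = e1))      # 8
  lapply(seq_along(defs), function(i) {
    u <- defs[[i]]$u; v <- defs[[i]]$v
    n <- c(u[2] * v[3] - u[3] * v[2],
           u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
    list(view_id = i - 1L, u = u, v = v, normal = n)
  })
}

#' Extract one oriented 2D patch by trilinear interpolation
#'
#' Sample grid \eqn{p(i, j) = center + (i - (size-1)/2)\,step\,u +
#' (j - (size-1)/2)\,step\,v}; samples outside the volume are zero-padded
#' (0 equals the normalized-background mean, so border candidates still
#' yield full, well-scaled patches). With the default \code{step_mm} equal
#' to the voxel pitch, a 65-sample patch spans 52 x 52 mm at 0.8 mm, the
#' in-plane extent of the cube that encloses the candidate.
#'
#' @param volume an \linkS4class{ImageVolume} (normally the normalized
#'   T1-like channel).
#' @param center_mm length-3 world position of the candidate in mm.
#' @param basis one element of \code{\link{enumerateViewBases}}.
#' @param size patch side in samples; must be odd and >= 3.
#' @param step_mm in-plane sample step; defaults to the voxel pitch.
#' @return \code{size x size} numeric matrix.
#' @export
extractPatch <- function(volume, center_mm, basis, size = 65L,
                         step_mm = NULL) {
  stopifnot(is(volume, "ImageVolume"), length(center_mm) == 3)
  if (size %% 2 == 0 || size < 3)
    stop("config error: patch size must be odd and >= 3")
  if (is.null(step_mm)) step_mm <- spacing(volume)
  .samplePlane(voxelData(volume), dim(volume), spacing(volume),
               as.numeric(center_mm), as.numeric(basis$u),
               as.numeric(basis$v), as.integer(size), step_mm)
}

#' Extract the 1-, 3- or 9-view patch set of a candidate
#'
#' @param volume an \linkS4class{ImageVolume}.
#' @param center_mm candidate position in mm (or a 1-row candidate
#'   data.frame with \code{pos_mm_x/y/z}).
#' @param n_views 1, 3 or 9.
#' @param size,step_mm see \code{\link{extractPatch}}.
#' @return list with \code{patches} (array \code{size x size x n_views}),
#'   \code{view_ids}, and \code{center_mm}.
#' @export
makeViewSet <- function(volume, center_mm, n_views = 9L, size = 65L,
                        step_mm = NULL) {
  if (is.data.frame(center_mm))
    center_mm <- c(center_mm$pos_mm_x[1], center_mm$pos_mm_y[1],
                   center_mm$pos_mm_z[1])
  if (!n_views %in% c(1L, 3L, 9L))
    stop("config error: n_views must be 1, 3 or 9")
  bases <- enumerateViewBases()[seq_len(n_views)]
  patches <- array(0, c(size, size, n_views))
  for (i in seq_along(bases))
    patches[, , i] <- extractPatch(volume, center_mm, bases[[i]], size,
                                   step_mm)
  list(patches = patches,
       view_ids = vapply(bases, `[[`, integer(1), "view_id"),
       center_mm = center_mm)
}

#' Patch array for a list of candidates
#'
#' Stacks the view sets of all candidates into the 4D array
#' \code{[size, size, n_views, n_candidates]} consumed by the network.
#'
#' @param volume an \linkS4class{ImageVolume}.
#' @param candidates data.frame with \code{pos_mm_x/y/z}.
#' @inheritParams makeViewSet
#' @return 4D numeric array.
#' @export
candidatePatchArray <- function(volume, candidates, n_views = 3L,
                                size = 65L, step_mm = NULL) {
  n <- nrow(candidates)
  out <- array(0, c(size, size, n_views, max(n, 0L)))
  for (i in seq_len(n)) {
    vs <- makeViewSet(volume,
                      c(candidates$pos_mm_x[i], candidates$pos_mm_y[i],
                        candidates$pos_mm_z[i]),
                      n_views, size, step_mm)
    out[, , , i] <- vs$patches
  }
  out
}
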