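# Independent brute-force oracles used to cross-check the fast
# implementations. These deliberately use naive loops and explicit
# definitions rather than the package's code paths.

# 26-connected component count of a logical 3D array (flood fill)
oracleComponentCount <- function(mask) {
  dims <- dim(mask)
  seen <- array(FALSE, dims)
  idx <- which(mask, arr.ind = TRUE)
  count <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    if (seen[v[1], v[2], v[3]]) next
    count <- count + 1L
    queue <- list(v)
    seen[v[1], v[2], v[3]] <- TRUE
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (o in seq_len(nrow(offs))) {
        nb <- cur + offs[o, ]
        if (any(nb < 1) || any(nb > dims)) next
        if (mask[nb[1], nb[2], nb[3]] && !seen[nb[1], nb[2], nb[3]]) {
          seen[nb[1], nb[2], nb[3]] <- TRUE
          queue[[length(queue) + 1L]] <- nb
        }
      }
    }
  }
  count
}

# Spherical-window local maxima + plateau merging, by explicit per-voxel
# distance checks (the full candidate-detection semantics, written naively)
oracleDetectCandidates <- function(L, spacing, window_diameter_mm = 10,
                                   floor = 0.01) {
  dims <- dim(L)
  r_mm <- window_diameter_mm / 2
  is_max <- array(FALSE, dims)
  for (k in seq_len(dims[3])) for (j in seq_len(dims[2]))
    for (i in seq_len(dims[1])) {
      if (!(L[i, j, k] > floor)) next
      ok <- TRUE
      rr <- ceiling(r_mm / spacing)
      for (dz in -rr:rr) for (dy in -rr:rr) for (dx in -rr:rr) {
        if (dx == 0 && dy == 0 && dz == 0) next
        if ((dx^2 + dy^2 + dz^2) * spacing^2 > r_mm^2 + 1e-12) next
        ii <- i + dx; jj <- j + dy; kk <- k + dz
        if (ii < 1 || ii > dims[1] || jj < 1 || jj > dims[2] ||
            kk < 1 || kk > dims[3]) next
        if (L[ii, jj, kk] > L[i, j, k]) { ok <- FALSE; break }
      }
      is_max[i, j, k] <- ok
    }
  cnt <- oracleComponentCount(is_max)
  # reduce each 26-connected component to the member nearest its centroid
  comp <- array(0L, dims)
  idx <- which(is_max, arr.ind = TRUE)
  nextc <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    if (comp[v[1], v[2], v[3]] > 0) next
    nextc <- nextc + 1L
    comp[v[1], v[2], v[3]] <- nextc
    queue <- list(v)
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (o in seq_len(nrow(offs))) {
        nb <- cur + offs[o, ]
        if (any(nb < 1) || any(nb > dims)) next
        if (is_max[nb[1], nb[2], nb[3]] && comp[nb[1], nb[2], nb[3]] == 0) {
          comp[nb[1], nb[2], nb[3]] <- nextc
          queue[[length(queue) + 1L]] <- nb
        }
      }
    }
  }
  out <- NULL
  for (cc in seq_len(nextc)) {
    m <- which(comp == cc, arr.ind = TRUE)
    ctr <- colMeans(m)
    d2 <- rowSums(sweep(m, 2, ctr)^2)
    o <- order(d2, m[, 1], m[, 2], m[, 3])
    pick <- m[o[1], ]
    out <- rbind(out, c(pick, L[pick[1], pick[2], pick[3]]))
  }
  if (is.null(out)) return(data.frame(index_x = integer(0),
                                      index_y = integer(0),
                                      index_z = integer(0),
                                      likelihood = numeric(0)))
  out <- data.frame(index_x = as.integer(out[, 1]),
                    index_y = as.integer(out[, 2]),
                    index_z = as.integer(out[, 3]), likelihood = out[, 4])
  out <- out[order(-out$likelihood, out$index_x, out$index_y, out$index_z), ]
  rownames(out) <- NULL
  out
}

# exhaustive search over all single-feature midpoint-threshold stumps by
# weighted squared error
oracleBestStump <- function(X, y, w) {
  best <- list(err = Inf)
  for (j in seq_len(ncol(X))) {
    u <- sort(unique(X[, j]))
    if (length(u) < 2) next
    for (t in (head(u, -1) + tail(u, -1)) / 2) {
      ge <- X[, j] >= t
      a <- sum(w[ge] * y[ge]) / sum(w[ge])
      b <- sum(w[!ge] * y[!ge]) / sum(w[!ge])
      pred <- ifelse(ge, a, b)
      err <- sum(w * (y - pred)^2)
      if (err < best$err - 1e-12) {
        best <- list(err = err, feature = j, threshold = t,
                     response_ge = a, response_lt = b)
      }
    }
  }
  best
}

# FROC operating points by per-threshold recounting
oracleFROC <- function(node_scores, fp_scores, n_nodes, n_images) {
  thr <- sort(unique(c(node_scores, fp_scores)), decreasing = TRUE)
  data.frame(
    threshold = thr,
    sensitivity = sapply(thr, function(t) sum(node_scores >= t)) / n_nodes,
    fp_per_node = sapply(thr, function(t) sum(fp_scores >= t)) / n_nodes,
    fp_per_image = sapply(thr, function(t) sum(fp_scores >= t)) / n_images)
}

# numeric integral of the piecewise-linear FROC (fine grid trapezoid)
oraclePAUC <- function(fp, sens, lo, hi, n_grid = 200001L) {
  o <- order(c(0, fp), c(0, sens))
  f <- approxfun(c(0, fp)[o], c(0, sens)[o], rule = 2, ties = max)
  x <- seq(lo, hi, length.out = n_grid)
  y <- f(x)
  sum((head(y, -1) + tail(y, -1)) / 2 * diff(x))
}

# deterministic separable patch task: bright blob (node-like) vs bright bar
# (vessel-like), at any patch size / view count
makePatchTask <- function(n_per_class, n_views, size = 65L, seed = 1L,
                          noise_sd = 0.3) {
  set.seed(seed)
  half <- (size - 1) / 2
  g <- seq(-half, half)
  arr <- array(rnorm(size * size * n_views * 2 * n_per_class, sd = noise_sd),
               c(size, size, n_views, 2 * n_per_class))
  lab <- integer(2 * n_per_class)
  for (i in seq_len(2 * n_per_class)) {
    blob <- i <= n_per_class
    lab[i] <- as.integer(blob)
    cx <- runif(1, -4, 4); cy <- runif(1, -4, 4)
    z <- if (blob)
      outer(g, g, function(a, b) 2 * exp(-((a - cx)^2 + (b - cy)^2) / 32))
    else
      outer(g, g, function(a, b) 2 * exp(-((a - cx)^2) / 32))
    for (v in seq_len(n_views)) arr[, , v, i] <- arr[, , v, i] + z
  }
  list(patches = arr, labels = lab)
}

# concatenate two [s,s,v,n] patch arrays along the sample axis
bindPatches <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1], d[2], d[3], d[4] + dim(b)[4]))
  if (d[4]) out[, , , seq_len(d[4])] <- a
  if (dim(b)[4]) out[, , , d[4] + seq_len(dim(b)[4])] <- b
  out
}

# small structured phantom used across tests (fast to generate)
testPhantom <- function(seed = 11L, ...) {
  generatePhantom(phantomConfig(seed = seed, ...))
}
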