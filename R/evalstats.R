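# FROC evaluation: candidate-to-annotation matching, FROC curves, partial
# AUC, patient-level bootstrap bands, one-sided bootstrap system comparison
# with Bonferroni correction, and stratified patient-level fold assignment.

#' Match candidates against an annotation label map
#'
#' A candidate whose voxel lies inside a node's segmentation is a hit for
#' that node; candidates outside all nodes are false positives. At any
#' threshold, a node counts as detected if at least one of its matched
#' candidates scores at or above the threshold; extra candidates inside an
#' already-counted node are ignored (neither TP nor FP), the standard FROC
#' hit convention that prevents double counting.
#'
#' @param candidates data.frame with \code{index_x/y/z} (1-based voxel
#'   indices).
#' @param annotation label-map \linkS4class{ImageVolume} on the same grid.
#' @return the candidates with a \code{node_label} column (NA for false
#'   positives).
#' @export
matchCandidates <- function(candidates, annotation) {
  stopifnot(is.data.frame(candidates), is(annotation, "ImageVolume"))
  a <- voxelData(annotation)
  dims <- dim(a)
  if (nrow(candidates)) {
    if (any(candidates$index_x < 1 | candidates$index_x > dims[1] |
            candidates$index_y < 1 | candidates$index_y > dims[2] |
            candidates$index_z < 1 | candidates$index_z > dims[3]))
      stop("grid mismatch: candidate voxel indices outside the annotation")
    lab <- a[cbind(candidates$index_x, candidates$index_y,
                   candidates$index_z)]
    candidates$node_label <- ifelse(lab > 0, lab, NA_integer_)
  } else candidates$node_label <- integer(0)
  candidates
}

# Pool per-image matched candidates into per-node best scores + FP scores.
# `images` is a list; each element needs: scores (numeric), node_label
# (NA = FP) and n_nodes (count of annotated nodes in that image).
.poolDetections <- function(images) {
  node_scores <- numeric(0)
  fp_scores <- numeric(0)
  n_nodes <- 0L
  for (im in images) {
    stopifnot(length(im$scores) == length(im$node_label))
    n_nodes <- n_nodes + im$n_nodes
    hit <- !is.na(im$node_label)
    if (any(hit)) {
      best <- tapply(im$scores[hit], im$node_label[hit], max)
      node_scores <- c(node_scores, as.numeric(best))
    }
    fp_scores <- c(fp_scores, im$scores[!hit])
  }
  list(node_scores = node_scores, fp_scores = fp_scores, n_nodes = n_nodes)
}

#' Build an FROC curve from matched candidates
#'
#' Operating points are taken at every distinct candidate score. At
#' threshold \eqn{t}: sensitivity is the fraction of annotated nodes with a
#' matched candidate scoring \eqn{\ge t}; false positives are unmatched
#' candidates scoring \eqn{\ge t}, normalized per node and per image.
#'
#' @param images list with one element per image, each a list with
#'   \code{scores}, \code{node_label} (NA for false positives; labels
#'   need only be unique within the image) and \code{n_nodes}. A single
#'   matched candidate data.frame plus \code{n_nodes} may be given instead.
#' @param n_nodes,n_images override the pooled normalizers (rarely needed).
#' @param score_column column used when a data.frame is supplied.
#' @return A \linkS4class{FROCCurve}.
#' @export
frocCurve <- function(images, n_nodes = NULL, n_images = NULL,
                      score_column = "likelihood") {
  if (is.data.frame(images)) {
    if (is.null(n_nodes)) stop("n_nodes is required with a data.frame input")
    images <- list(list(scores = images[[score_column]],
                        node_label = images$node_label, n_nodes = n_nodes))
  }
  if (is.null(n_images)) n_images <- length(images)
  pooled <- .poolDetections(images)
  if (is.null(n_nodes)) n_nodes <- pooled$n_nodes
  if (n_nodes < 1) stop("FROC requires at least one annotated node")
  thr <- sort(unique(c(pooled$node_scores, pooled$fp_scores)),
              decreasing = TRUE)
  if (!length(thr))
    return(new("FROCCurve", thresholds = numeric(0), sensitivity = numeric(0),
               fpPerNode = numeric(0), fpPerImage = numeric(0),
               nNodes = as.integer(n_nodes), nImages = as.integer(n_images)))
  # every score occurs in thr, so counts >= t follow from cumulative tallies
  nT <- length(thr)
  sens <- cumsum(tabulate(match(pooled$node_scores, thr), nbins = nT)) /
    n_nodes
  nfp <- cumsum(tabulate(match(pooled$fp_scores, thr), nbins = nT))
  new("FROCCurve", thresholds = thr, sensitivity = sens,
      fpPerNode = nfp / n_nodes, fpPerImage = nfp / n_images,
      nNodes = as.integer(n_nodes), nImages = as.integer(n_images))
}

# piecewise-linear sensitivity as a function of FP/node, anchored at the
# (0, 0) operating point (threshold above every score) and extended beyond
# the last point with the last sensitivity
.frocInterp <- function(curve) {
  fp <- c(0, curve@fpPerNode)
  se <- c(0, curve@sensitivity)
  o <- order(fp, se)
  approxfun(fp[o], se[o], rule = 2, ties = max)
}

#' Partial area under the FROC curve
#'
#' Trapezoidal integral of sensitivity (as a fraction) against false
#' positives per node on a linear axis between \code{fp_lo} and
#' \code{fp_hi}, with linear interpolation at the bounds and step extension
#' with the last sensitivity beyond the last operating point. The maximum
#' attainable value is \code{fp_hi - fp_lo} (31.75 for the default
#' 0.25-32 range).
#'
#' @param curve a \linkS4class{FROCCurve}.
#' @param fp_lo,fp_hi integration bounds in FP per node.
#' @return numeric partial AUC.
#' @export
partialAUC <- function(curve, fp_lo = 0.25, fp_hi = 32) {
  if (fp_lo >= fp_hi) stop("config error: fp_lo must be below fp_hi")
  f <- .frocInterp(curve)
  knots <- sort(unique(c(fp_lo, fp_hi,
                         curve@fpPerNode[curve@fpPerNode > fp_lo &
                                         curve@fpPerNode < fp_hi])))
  x <- knots
  y <- f(x)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' False positives at a target sensitivity
#'
#' Smallest false-positive rate at which the (piecewise-linear) FROC curve
#' reaches the target sensitivity; \code{NA} if the curve never reaches it.
#'
#' @param curve a \linkS4class{FROCCurve}.
#' @param sensitivity target sensitivity as a fraction (default 0.80).
#' @param per \code{"image"} or \code{"node"}.
#' @return numeric FP rate.
#' @export
fpAtSensitivity <- function(curve, sensitivity = 0.8,
                            per = c("image", "node")) {
  per <- match.arg(per)
  fp <- c(0, if (per == "image") curve@fpPerImage else curve@fpPerNode)
  se <- c(0, curve@sensitivity)
  o <- order(fp, se)
  fp <- fp[o]; se <- se[o]
  if (max(se) < sensitivity) return(NA_real_)
  i <- which(se >= sensitivity)[1]
  if (i == 1 || se[i] == sensitivity || fp[i] == fp[i - 1]) return(fp[i])
  fp[i - 1] + (sensitivity - se[i - 1]) / (se[i] - se[i - 1]) *
    (fp[i] - fp[i - 1])
}

#' Patient-level bootstrap of FROC curves and partial AUCs
#'
#' Resamples patients with replacement; every replicate recomputes the
#' pooled FROC curve and partial AUC for each system on the same resampled
#' patient set, so per-replicate pAUCs are paired across systems.
#' Confidence bands are percentile 2.5/97.5 bands of sensitivity at fixed
#' FP-per-node abscissae. Deterministic for a fixed seed.
#'
#' @param systems named list of systems; each system is a list with one
#'   element per patient as in \code{\link{frocCurve}}.
#' @param n_boot number of bootstrap replicates.
#' @param fp_range pAUC bounds in FP/node.
#' @param abscissae FP/node positions for the sensitivity bands.
#' @param seed RNG seed.
#' @return list: \code{pauc} (point estimate, CI per system),
#'   \code{pauc_reps} (n_boot x n_systems matrix), \code{bands} (per
#'   system: abscissae, lo, hi, point), \code{n_boot}, \code{seed}.
#' @export
bootstrapFROC <- function(systems, n_boot = 1000L, fp_range = c(0.25, 32),
                          abscissae = NULL, seed = 1L) {
  stopifnot(is.list(systems), length(systems) >= 1)
  if (is.null(names(systems)))
    names(systems) <- paste0("system", seq_along(systems))
  n_pat <- length(systems[[1]])
  if (any(vapply(systems, length, integer(1)) != n_pat))
    stop("all systems must cover the same patients")
  if (n_pat < 2) stop("degenerate error: bootstrap needs >= 2 patients")
  if (is.null(abscissae))
    abscissae <- exp(seq(log(fp_range[1]), log(fp_range[2]),
                         length.out = 40))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  reps <- matrix(NA_real_, n_boot, length(systems),
                 dimnames = list(NULL, names(systems)))
  sens_reps <- lapply(systems, function(s)
    matrix(NA_real_, n_boot, length(abscissae)))
  for (b in seq_len(n_boot)) {
    take <- sample.int(n_pat, n_pat, replace = TRUE)
    for (k in seq_along(systems)) {
      cur <- frocCurve(systems[[k]][take], n_images = n_pat)
      reps[b, k] <- partialAUC(cur, fp_range[1], fp_range[2])
      sens_reps[[k]][b, ] <- .frocInterp(cur)(abscissae)
    }
  }
  point <- lapply(systems, function(s) frocCurve(s))
  pauc <- data.frame(
    system = names(systems),
    pauc = vapply(point, partialAUC, numeric(1),
                  fp_lo = fp_range[1], fp_hi = fp_range[2]),
    ci_lo = apply(reps, 2, quantile, 0.025),
    ci_hi = apply(reps, 2, quantile, 0.975))
  rownames(pauc) <- NULL
  bands <- lapply(seq_along(systems), function(k) {
    data.frame(fp_per_node = abscissae,
               sensitivity = .frocInterp(point[[k]])(abscissae),
               ci_lo = apply(sens_reps[[k]], 2, quantile, 0.025),
               ci_hi = apply(sens_reps[[k]], 2, quantile, 0.975))
  })
  names(bands) <- names(systems)
  list(pauc = pauc, pauc_reps = reps, bands = bands, curves = point,
       n_boot = as.integer(n_boot), fp_range = fp_range, seed = seed)
}

#' One-sided paired bootstrap comparison of two systems
#'
#' Tests whether system B outperforms system A on partial AUC using paired
#' bootstrap replicates (same resampled patients per replicate). The raw
#' one-sided p-value is the fraction of replicates in which B does not beat
#' A, with the small-sample correction \eqn{(count + 1)/(n + 1)}; the
#' Bonferroni-adjusted p-value is \eqn{\min(1, p \cdot m)} for \eqn{m}
#' comparisons.
#'
#' @param pauc_reps_A,pauc_reps_B per-replicate pAUC vectors of equal
#'   length, paired by replicate.
#' @param n_comparisons Bonferroni multiplier \eqn{m}.
#' @return list with \code{p_raw} and \code{p_adjusted}.
#' @export
compareSystems <- function(pauc_reps_A, pauc_reps_B, n_comparisons = 1L) {
  if (length(pauc_reps_A) != length(pauc_reps_B))
    stop("unpaired replicate counts")
  n <- length(pauc_reps_A)
  p_raw <- (sum(pauc_reps_B <= pauc_reps_A) + 1) / (n + 1)
  list(p_raw = p_raw, p_adjusted = min(1, p_raw * n_comparisons))
}

#' Stratified patient-level fold assignment
#'
#' Greedy balancing of annotated-node counts across folds: patients are
#' sorted by node count (descending, ties shuffled by the seed) and each is
#' assigned to the currently lightest fold. Within a cross-validation run,
#' three folds train, one validates and one tests; the five runs' test
#' predictions are pooled for analysis.
#'
#' @param node_counts named integer vector: annotated nodes per patient.
#' @param k number of folds.
#' @param seed RNG seed for tie shuffling.
#' @return list: \code{fold} (named assignment, folds 1..k),
#'   \code{fold_node_counts}, and \code{schedule} (data.frame run,
#'   test_fold, val_fold).
#' @export
stratifiedPatientFolds <- function(node_counts, k = 5L, seed = 1L) {
  n <- length(node_counts)
  if (n < k) stop("fewer patients than folds")
  if (is.null(names(node_counts)))
    names(node_counts) <- paste0("patient", seq_len(n))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  o <- order(-node_counts, sample.int(n))  # ties shuffled
  fold <- integer(n)
  load <- numeric(k)
  size <- integer(k)
  for (i in o) {
    # lightest fold by node load; break ties by fewest patients, then index
    cand <- which(load == min(load))
    if (length(cand) > 1) cand <- cand[which.min(size[cand])]
    f <- cand[1]
    fold[i] <- f
    load[f] <- load[f] + node_counts[i]
    size[f] <- size[f] + 1L
  }
  names(fold) <- names(node_counts)
  schedule <- data.frame(run = seq_len(k), test_fold = seq_len(k),
                         val_fold = c(seq_len(k)[-1], 1L))
  list(fold = fold, fold_node_counts = as.numeric(load), schedule = schedule)
}

#' Read a raw FROC curve table
#'
#' Reads externally produced FROC operating points (for example, published
#' supplementary raw-curve data) with automatic delimiter detection among
#' comma, semicolon, tab and whitespace. The first two numeric columns are
#' interpreted as the false-positive rate and sensitivity; a header row is
#' detected automatically. Sensitivities given in percent are rescaled to
#' fractions.
#'
#' @param path file path.
#' @param fp_unit unit of the FP column: \code{"node"} or \code{"image"}.
#' @return data.frame with columns \code{fp} and \code{sensitivity}
#'   (fraction), sorted by \code{fp}, with attribute \code{fp_unit}.
#' @export
readFROCTable <- function(path, fp_unit = c("node", "image")) {
  fp_unit <- match.arg(fp_unit)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty FROC table: ", path)
  probe <- lines[min(2, length(lines))]
  counts <- c(comma = lengths(regmatches(probe, gregexpr(",", probe))),
              semi = lengths(regmatches(probe, gregexpr(";", probe))),
              tab = lengths(regmatches(probe, gregexpr("\t", probe))))
  sep <- switch(names(which.max(counts)),
                comma = ",", semi = ";", tab = "\t")
  if (max(counts) == 0) sep <- ""
  first <- strsplit(trimws(lines[1]), if (nzchar(sep)) sep else "[[:space:]]+")[[1]]
  header <- any(is.na(suppressWarnings(as.numeric(first))))
  df <- read.table(text = paste(lines, collapse = "\n"), sep = sep,
                   header = header, strip.white = TRUE)
  num <- df[vapply(df, is.numeric, logical(1))]
  if (ncol(num) < 2) stop("expected at least two numeric columns")
  out <- data.frame(fp = num[[1]], sensitivity = num[[2]])
  if (max(out$sensitivity) > 1.5) out$sensitivity <- out$sensitivity / 100
  out <- out[order(out$fp), ]
  rownames(out) <- NULL
  attr(out, "fp_unit") <- fp_unit
  out
}

#' FROC curve from an external operating-point table
#'
#' @param table output of \code{\link{readFROCTable}}.
#' @param n_nodes,n_images normalizers; when the table's FP unit differs
#'   from per-node, both are required to convert.
#' @return A \linkS4class{FROCCurve} suitable for \code{\link{partialAUC}}
#'   and \code{\link{fpAtSensitivity}}.
#' @export
frocFromTable <- function(table, n_nodes = 1L, n_images = 1L) {
  unit <- attr(table, "fp_unit")
  if (is.null(unit)) unit <- "node"
  fp_node <- if (unit == "node") table$fp else table$fp * n_images / n_nodes
  fp_image <- if (unit == "image") table$fp else table$fp * n_nodes / n_images
  o <- order(-table$fp)
  new("FROCCurve",
      thresholds = seq(1, 0, length.out = nrow(table)),
      sensitivity = sort(table$sensitivity),
      fpPerNode = sort(fp_node), fpPerImage = sort(fp_image),
      nNodes = as.integer(n_nodes), nImages = as.integer(n_images))
}
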