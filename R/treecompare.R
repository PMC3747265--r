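#' Paired distances between two matrices over their shared ids
#'
#' One (x, y) tuple per unordered pair of ids present in both matrices; ids
#' missing from either matrix are dropped (logged).
#'
#' @param dm_ref reference (e.g. nearly-full-length) distance matrix
#' @param dm_cmp comparison (e.g. short-read) distance matrix
#' @return data frame with columns `id1`, `id2`, `x` (ref), `y` (cmp)
#' @export
pair_distances <- function(dm_ref, dm_cmp) {
  shared <- intersect(rownames(dm_ref), rownames(dm_cmp))
  dropped <- length(union(rownames(dm_ref), rownames(dm_cmp))) - length(shared)
  if (dropped > 0L) pe_log("info", "pair_distances: dropped %d unshared id(s)", dropped)
  if (length(shared) < 3L) stop("value error: need >= 3 shared ids")
  shared <- sort(shared)
  idx <- which(upper.tri(diag(length(shared))), arr.ind = TRUE)
  data.frame(id1 = shared[idx[, 1]], id2 = shared[idx[, 2]],
             x = dm_ref[shared, shared][idx],
             y = dm_cmp[shared, shared][idx],
             stringsAsFactors = FALSE)
}

#' Pearson correlation of paired distances
#' @param pd data frame from [pair_distances()] (or any with x, y)
#' @return correlation in \[-1, 1\], or NA when either coordinate has zero
#'   variance
#' @export
pearson <- function(pd) {
  if (nrow(pd) < 2L) stop("value error: need >= 2 tuples")
  if (stats::sd(pd$x) == 0 || stats::sd(pd$y) == 0) {
    pe_log("warn", "pearson undefined (zero variance); returning NA")
    return(NA_real_)
  }
  stats::cor(pd$x, pd$y)
}

#' Slope of the least-squares line forced through the origin
#'
#' `b = sum(x*y) / sum(x^2)`: how strongly comparison distances inflate
#' (b > 1) or shrink (b < 1) relative to the reference.
#'
#' @param pd paired distances
#' @return non-negative real for non-negative inputs
#' @export
slope_through_origin <- function(pd) {
  sx2 <- sum(pd$x^2)
  if (sx2 == 0) stop("value error: all x are zero")
  sum(pd$x * pd$y) / sx2
}

#' Binned profile of comparison distances along the reference axis
#'
#' Bins `[k*w, (k+1)*w)` over the (normalized) reference distance; per bin
#' the count, mean and sample (n-1) standard deviation of the comparison
#' distances. Single-member bins report `sd = NA`; empty bins are omitted.
#' Bins with reference distance above `flag_above` are marked as excluded
#' from resolving-power interpretation (still computed and emitted).
#'
#' @param pd paired distances with x in \[0, 1\]
#' @param width bin width (default 0.01)
#' @param flag_above reference distance beyond which bins are flagged
#' @return data frame: bin_start, bin_end, count, mean, sd, flagged
#' @export
binned_profile <- function(pd, width = 0.01, flag_above = 0.8) {
  if (width <= 0) stop("value error: width must be > 0")
  bin <- floor(pd$x / width)
  agg <- split(pd$y, bin)
  bins <- as.integer(names(agg))
  out <- data.frame(
    bin_start = bins * width,
    bin_end = (bins + 1L) * width,
    count = lengths(agg),
    mean = vapply(agg, mean, 0),
    sd = vapply(agg, function(v) if (length(v) > 1L) stats::sd(v) else NA_real_, 0)
  )
  out <- out[order(out$bin_start), , drop = FALSE]
  out$flagged <- out$bin_start >= flag_above
  rownames(out) <- NULL
  out
}

#' Classical (Torgerson) metric MDS embedding
#'
#' Double-centers the squared-distance matrix, takes the top eigenpairs, and
#' scales eigenvectors by the square roots of the (clamped non-negative)
#' eigenvalues. Axes are ordered by descending eigenvalue and each axis's
#' sign is fixed so its largest-magnitude coordinate is positive, making the
#' embedding deterministic.
#'
#' @param dm distance matrix
#' @param dims embedding dimensionality (1 <= dims <= n-1)
#' @return n x dims coordinate matrix (ids as rownames)
#' @export
mds_embed <- function(dm, dims = 3L) {
  check_distance_matrix(dm)
  n <- nrow(dm)
  if (dims < 1L || dims > n - 1L) stop("value error: dims must be in [1, n-1]")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (dm^2) %*% J
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  lam <- pmax(eg$values[seq_len(dims)], 0)
  X <- eg$vectors[, seq_len(dims), drop = FALSE] %*% diag(sqrt(lam), dims)
  for (k in seq_len(dims)) {
    i <- which.max(abs(X[, k]))
    if (X[i, k] < 0) X[, k] <- -X[, k]
  }
  rownames(X) <- rownames(dm)
  X
}

#' Weighted RMSD after optimal superposition (Procrustes, no scaling)
#'
#' Removes the weighted centroids, finds the weighted orthogonal
#' transformation (rotation or reflection) minimizing the weighted squared
#' deviation, and reports `sqrt(sum(w * ||x - y'||^2) / sum(w))`. No scaling
#' step: both configurations are expected to come from matrices normalized
#' upstream, and scaling would absorb exactly the branch-length inflation the
#' slope statistic measures. Lower values mean a better fit.
#'
#' @param points_ref,points_cmp n x d coordinate matrices
#' @param weights optional non-negative weights (default uniform)
#' @return non-negative real
#' @export
wrmsd_superimpose <- function(points_ref, points_cmp, weights = NULL) {
  X <- as.matrix(points_ref); Y <- as.matrix(points_cmp)
  if (!all(dim(X) == dim(Y))) stop("value error: mismatched shapes")
  n <- nrow(X)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) == 0) {
    stop("value error: weights must be non-negative and not all zero")
  }
  w <- weights / sum(weights)
  Xc <- sweep(X, 2L, colSums(X * w))
  Yc <- sweep(Y, 2L, colSums(Y * w))
  C <- t(Xc * w) %*% Yc
  sv <- svd(C)
  R <- sv$v %*% t(sv$u)      # reflections allowed
  Yr <- Yc %*% R
  sqrt(sum(w * rowSums((Xc - Yr)^2)))
}

#' Full branch-length and topology comparison of two trees
#'
#' Pipelines: patristic matrices -> max-1 normalization -> paired distances
#' -> Pearson r and through-origin slope; normalized matrices -> MDS
#' embedding -> Procrustes wRMSD; trees -> RF/WRF1/WRF2.
#'
#' @param t_ref,t_cmp trees sharing >= 4 leaves (pruned to the shared set)
#' @param dims MDS dimensionality (reduced to n-1 when larger)
#' @param weights optional wRMSD weights
#' @return object of class `tree_comparison`: list with pearson_r, slope,
#'   wrmsd, rf, wrf1, wrf2, n_shared
#' @export
compare_trees <- function(t_ref, t_cmp, dims = 3L, weights = NULL) {
  shared <- intersect(t_ref$tip.label, t_cmp$tip.label)
  if (length(shared) < 4L) stop("value error: need >= 4 shared leaves")
  if (length(shared) < length(t_ref$tip.label)) {
    t_ref <- ape::keep.tip(t_ref, shared)
  }
  if (length(shared) < length(t_cmp$tip.label)) {
    t_cmp <- ape::keep.tip(t_cmp, shared)
  }
  d_ref <- normalize_max1(patristic_matrix(t_ref))
  d_cmp <- normalize_max1(patristic_matrix(t_cmp))
  pd <- pair_distances(d_ref, d_cmp)
  dims <- min(dims, length(shared) - 1L)
  ids <- sort(shared)
  e_ref <- mds_embed(d_ref[ids, ids], dims)
  e_cmp <- mds_embed(d_cmp[ids, ids], dims)
  structure(list(
    pearson_r = pearson(pd),
    slope = slope_through_origin(pd),
    wrmsd = wrmsd_superimpose(e_ref, e_cmp, weights),
    rf = rf_distance(t_ref, t_cmp),
    wrf1 = wrf1(t_ref, t_cmp),
    wrf2 = wrf2(t_ref, t_cmp),
    n_shared = length(shared)
  ), class = "tree_comparison")
}

#' @export
print.tree_comparison <- function(x, ...) {
  cat(sprintf(paste0("tree comparison over %d shared leaves:\n",
                     "  Pearson r  %.4f\n  slope      %.4f\n  wRMSD      %.6f\n",
                     "  RF %d   WRF1 %.4f   WRF2 %.4f\n"),
              x$n_shared, x$pearson_r, x$slope, x$wrmsd, x$rf, x$wrf1, x$wrf2))
  invisible(x)
}
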