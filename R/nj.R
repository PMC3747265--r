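#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration. Negative branch-length estimates are
#' clamped to zero with the deficit moved to the sister edge. The result is
#' deterministic for a given matrix: ties in the Q criterion are broken on
#' the lexicographically smallest (label, label) pair, where a merged
#' cluster inherits its smallest member label.
#'
#' @param dm symmetric distance matrix with >= 3 unique ids
#' @return unrooted `ape::phylo`
#' @export
neighbor_joining <- function(dm) {
  check_distance_matrix(dm)
  n0 <- nrow(dm)
  if (n0 < 3L) stop("value error: need >= 3 taxa")
  labels <- rownames(dm)
  frags <- stats::setNames(as.list(labels), labels)   # newick fragments
  keys <- stats::setNames(labels, labels)             # tie-break keys
  D <- dm
  while (nrow(D) > 3L) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    ck <- apply(cand, 1L, function(idx) {
      k <- sort(c(keys[rownames(D)[idx[1]]], keys[rownames(D)[idx[2]]]))
      paste(k, collapse = "\r")
    })
    pick <- cand[order(ck)[1], ]
    i <- pick[1]; j <- pick[2]
    dij <- D[i, j]
    vi <- 0.5 * dij + (r[i] - r[j]) / (2 * (n - 2))
    vj <- dij - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- max(0, vi + vj); vj <- 0 }
    li <- rownames(D)[i]; lj <- rownames(D)[j]
    newfrag <- sprintf("(%s:%.15g,%s:%.15g)", frags[[li]], vi, frags[[lj]], vj)
    newkey <- min(keys[li], keys[lj])
    newlab <- paste0("_c", length(frags) + 1L)
    dnew <- 0.5 * (D[i, -c(i, j), drop = TRUE] + D[j, -c(i, j), drop = TRUE] - dij)
    dnew <- pmax(dnew, 0)
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew), c(dnew, 0))
    rownames(D2) <- colnames(D2) <- c(rownames(D)[keep], newlab)
    D <- D2
    frags[[newlab]] <- newfrag
    keys[newlab] <- newkey
  }
  l <- rownames(D)
  a <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  c3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  v <- pmax(c(a, b, c3), 0)
  nwk <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 frags[[l[1]]], v[1], frags[[l[2]]], v[2], frags[[l[3]]], v[3])
  ape::read.tree(text = nwk)
}

#' A star tree (single multifurcation) on a set of labels
#' @param labels tip labels
#' @param edge_length pendant edge length
#' @return `ape::phylo`
#' @export
star_tree <- function(labels, edge_length = 0) {
  nwk <- paste0("(", paste(sprintf("%s:%.15g", labels, edge_length), collapse = ","), ");")
  ape::read.tree(text = nwk)
}

#' Bootstrap supports for a distance tree
#'
#' Builds the main tree from the full alignment, then resamples alignment
#' columns with replacement `n_replicates` times, rebuilding a tree per
#' replicate; the support of each internal edge is the fraction of replicate
#' trees containing its bipartition, stored in `node.label` on a \[0, 1\]
#' scale. If the full alignment yields an all-zero distance matrix (no
#' resolved signal) a star tree is returned.
#'
#' @param library aligned [seq_library()]
#' @param n_replicates number of bootstrap replicates (default 500)
#' @param seed integer seed
#' @param model distance model passed to [pairwise_seq_distance()]
#' @param tree_builder function(distance matrix) -> phylo (default NJ)
#' @return `ape::phylo` with supports in `node.label`
#' @export
bootstrap_supports <- function(library, n_replicates = 500L, seed = 1L,
                               model = "jc", tree_builder = neighbor_joining) {
  if (n_replicates < 1L) stop("value error: n_replicates must be >= 1")
  dm <- pairwise_seq_distance(library, model = model, on_saturation = "cap")
  if (max(dm) == 0) {
    pe_log("warn", "degenerate library (all sequences identical): star tree")
    return(star_tree(rownames(dm)))
  }
  main <- tree_builder(dm)
  main_splits <- tree_splits(main)
  counts <- stats::setNames(numeric(nrow(main_splits)), main_splits$key)
  L <- alignment_length(library)
  with_seed(derive_seed(seed, "bootstrap"), {
    for (b in seq_len(n_replicates)) {
      cols <- sample.int(L, L, replace = TRUE)
      dmb <- tryCatch(
        pairwise_seq_distance(library, model = model, on_saturation = "cap",
                              columns = cols),
        error = function(e) NULL)
      if (is.null(dmb)) next
      if (max(dmb) == 0) next
      trb <- tree_builder(dmb)
      kb <- tree_splits(trb)$key
      hit <- main_splits$key %in% kb
      counts[hit] <- counts[hit] + 1
    }
  })
  support <- counts / n_replicates
  ## write supports onto internal node labels of the main tree
  main$node.label <- rep("", main$Nnode)
  ntip <- length(main$tip.label)
  for (i in seq_len(nrow(main_splits))) {
    main$node.label[main_splits$node[i] - ntip] <- fmt_num(support[i])
  }
  main
}
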