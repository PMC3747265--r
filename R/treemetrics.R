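#' Patristic distance matrix of a tree
#'
#' Sum of branch lengths along the path between every pair of leaves.
#'
#' @param tree `ape::phylo` with branch lengths
#' @return symmetric matrix over tip labels
#' @export
patristic_matrix <- function(tree) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("value error: tree must have complete branch lengths")
  }
  nd <- ape::dist.nodes(tree)
  ntip <- length(tree$tip.label)
  d <- nd[seq_len(ntip), seq_len(ntip), drop = FALSE]
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge induces a two-way split of the leaf set; the canonical
#' form is the side containing the lexicographically smallest leaf label, and
#' splits with a singleton side are excluded. Each split carries the support
#' parsed from the child node's label (NA where absent).
#'
#' @param tree `ape::phylo`
#' @return data frame with columns `key` (canonical side, `|`-joined sorted
#'   labels), `support`, `node` (internal node id in the unrooted tree)
#' @export
tree_splits <- function(tree) {
  ## work on the tree as stored: in a rooted binary tree the two root
  ## children carry the same split, and only one of them may hold the
  ## support label, so duplicates are merged with a preference for the
  ## labelled node rather than unrooted first (which could drop the label)
  tr <- tree
  ntip <- length(tr$tip.label)
  min_tip <- min(tr$tip.label)
  sup <- tree_supports(tr)
  pp <- ape::prop.part(tr)
  rows <- list()
  for (nd in seq_along(pp)) {
    node <- ntip + nd
    tips <- tr$tip.label[pp[[nd]]]
    sz <- length(tips)
    if (sz <= 1L || sz >= ntip - 1L) next
    side <- if (min_tip %in% tips) tips else setdiff(tr$tip.label, tips)
    rows[[length(rows) + 1L]] <- data.frame(
      key = paste(sort(side), collapse = "|"),
      support = sup[nd], node = node, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(key = character(), support = numeric(), node = integer()))
  }
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$key)) {
    keep <- vapply(split(seq_len(nrow(out)), out$key), function(idx) {
      lab <- idx[!is.na(out$support[idx])]
      if (length(lab)) lab[1] else idx[1]
    }, 0L)
    out <- out[sort(keep), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

.check_same_leaves <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("value error: trees have different leaf sets")
  }
}

#' Robinson-Foulds distance
#'
#' Number of non-trivial bipartitions present in one tree but not the other.
#'
#' @param t1,t2 `ape::phylo` on the same leaf set
#' @return integer
#' @export
rf_distance <- function(t1, t2) {
  .check_same_leaves(t1, t2)
  k1 <- tree_splits(t1)$key
  k2 <- tree_splits(t2)$key
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

.wrf_splits <- function(tree, default_support) {
  s <- tree_splits(tree)
  if (any(!is.na(s$support) & (s$support < 0 | s$support > 1))) {
    stop("value error: supports must lie in [0, 1]")
  }
  s$support[is.na(s$support)] <- default_support
  s
}

#' Weighted Robinson-Foulds distance (WRF1)
#'
#' Like [rf_distance()] but each unique bipartition contributes its bootstrap
#' support instead of 1, so weakly supported conflicts are penalized less (a
#' split supported at 0.6 counts 0.6). Missing supports default to 1, which
#' recovers the unweighted metric exactly.
#'
#' @param t1,t2 trees on the same leaf set, supports in \[0, 1\]
#' @param default_support value used where a split carries no support
#' @return non-negative real
#' @export
wrf1 <- function(t1, t2, default_support = 1) {
  .check_same_leaves(t1, t2)
  s1 <- .wrf_splits(t1, default_support)
  s2 <- .wrf_splits(t2, default_support)
  sum(s1$support[!s1$key %in% s2$key]) + sum(s2$support[!s2$key %in% s1$key])
}

#' Weighted Robinson-Foulds distance with shared-split support differences (WRF2)
#'
#' [wrf1()] plus, for every bipartition shared by both trees, the absolute
#' difference of its two support values.
#'
#' @inheritParams wrf1
#' @return non-negative real, always >= `wrf1(t1, t2)`
#' @export
wrf2 <- function(t1, t2, default_support = 1) {
  .check_same_leaves(t1, t2)
  s1 <- .wrf_splits(t1, default_support)
  s2 <- .wrf_splits(t2, default_support)
  shared <- intersect(s1$key, s2$key)
  base <- sum(s1$support[!s1$key %in% s2$key]) + sum(s2$support[!s2$key %in% s1$key])
  base + sum(abs(s1$support[match(shared, s1$key)] - s2$support[match(shared, s2$key)]))
}
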