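#' Sliding-window phylogenetic placement profile
#'
#' For each window of alignment columns and each taxon: the taxon is removed
#' from the reference tree, its p-distances to the remaining taxa are
#' computed from the window columns only (pairwise deletion), and it is
#' re-attached to the edge minimizing the least-squares disagreement between
#' window-implied and tree-implied distances (pendant length and attachment
#' point fitted per candidate edge). The reported node distance is the
#' number of nodes separating the original attachment edge from the chosen
#' one (0 when the window places the taxon back on its own edge). This is a
#' distance-based surrogate for likelihood re-insertion: it preserves the
#' meaning of the statistic (how far short-window information displaces a
#' taxon) at desk scale.
#'
#' @param library aligned [seq_library()]
#' @param tree `ape::phylo` on the same ids, with branch lengths
#' @param window window size in alignment columns (default 280); windows
#'   longer than the alignment collapse to one full-length window
#' @param step column step between window starts (default: at most 9 windows)
#' @return list with `profile` (data frame: window_start, window_end,
#'   mean_node_dist) and `per_taxon` (taxa x windows matrix of node distances)
#' @export
sliding_window_placement <- function(library, tree, window = 280L, step = NULL) {
  ids <- names(library$seqs)
  if (length(ids) < 4L) stop("value error: need >= 4 taxa")
  if (!setequal(ids, tree$tip.label)) stop("value error: tree and library ids differ")
  L <- alignment_length(library)
  if (window >= L) { window <- L }
  if (is.null(step)) step <- max(1L, as.integer(floor((L - window) / 8)))
  starts <- unique(c(seq(1L, L - window + 1L, by = step)))
  tr <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  attributes(tr) <- attributes(tr)[c("names", "class")]

  prep <- lapply(ids, function(id) .placement_prep(tr, id))
  names(prep) <- ids

  per_taxon <- matrix(NA_real_, nrow = length(ids), ncol = length(starts),
                      dimnames = list(ids, NULL))
  for (wi in seq_along(starts)) {
    cols <- starts[wi]:(starts[wi] + window - 1L)
    dmw <- pairwise_seq_distance(library, model = "p", columns = cols)
    for (id in ids) {
      pp <- prep[[id]]
      d <- dmw[id, pp$tips]
      best <- .ls_attach(pp, d)
      per_taxon[id, wi] <- pp$edge_dist[best]
    }
  }
  profile <- data.frame(window_start = starts,
                        window_end = starts + window - 1L,
                        mean_node_dist = colMeans(per_taxon))
  list(profile = profile, per_taxon = per_taxon)
}

## Precompute, for one dropped taxon: the pruned tree's node distances, the
## per-edge leaf sides, the original attachment edge, and node distances
## from it to every edge (edges adjacent when they share a node).
.placement_prep <- function(tr, tip_id) {
  ntip_full <- length(tr$tip.label)
  tip <- match(tip_id, tr$tip.label)
  v <- tr$edge[tr$edge[, 2] == tip, 1]
  ## adjacency of the full tree
  adj <- .tree_adjacency(tr)
  nbrs <- setdiff(adj[[v]], tip)
  pruned <- ape::drop.tip(tr, tip_id)
  ## a degree-2 root would split the merged attachment edge in two
  if (ape::is.rooted(pruned)) pruned <- ape::unroot(pruned)
  ptips <- pruned$tip.label
  min_tip <- min(ptips)
  ## reference side: tips reachable from nbrs[1] without crossing v
  side_tips <- intersect(tr$tip.label[.reach_tips(adj, nbrs[1], v, ntip_full)],
                         ptips)
  orig_key <- .canon_key(side_tips, ptips, min_tip)

  nd <- ape::dist.nodes(pruned)
  np <- length(ptips)
  edges <- pruned$edge
  elen <- pruned$edge.length
  padj <- .tree_adjacency(pruned)
  below <- lapply(seq_len(nrow(edges)), function(e) {
    .reach_tips(padj, edges[e, 2], edges[e, 1], np)
  })
  keys <- vapply(below, function(b) .canon_key(ptips[b], ptips, min_tip), "")
  orig_edge <- match(orig_key, keys)
  if (is.na(orig_edge)) {
    ## multifurcation fallback: nearest edge incident to the old neighbor
    orig_edge <- which(edges[, 1] %in% nbrs | edges[, 2] %in% nbrs)[1]
  }
  ## BFS over the edge-adjacency graph
  nedge <- nrow(edges)
  edist <- rep(NA_real_, nedge)
  edist[orig_edge] <- 0
  frontier <- orig_edge
  while (length(frontier)) {
    nxt <- integer(0)
    for (e in frontier) {
      touch <- which((edges[, 1] %in% edges[e, ]) | (edges[, 2] %in% edges[e, ]))
      new <- touch[is.na(edist[touch])]
      edist[new] <- edist[e] + 1
      nxt <- c(nxt, new)
    }
    frontier <- nxt
  }
  side_v <- lapply(below, function(b) seq_len(np) %in% b)
  list(tips = ptips, nd = nd, edges = edges, elen = elen,
       side_v = side_v, edge_dist = edist, orig_edge = orig_edge)
}

.tree_adjacency <- function(tr) {
  nn <- length(tr$tip.label) + tr$Nnode
  adj <- vector("list", nn)
  for (e in seq_len(nrow(tr$edge))) {
    a <- tr$edge[e, 1]; b <- tr$edge[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

## tips reachable from `from` without stepping onto `block`
.reach_tips <- function(adj, from, block, ntip) {
  seen <- c(from, block)
  frontier <- from
  tips <- from[from <= ntip]
  while (length(frontier)) {
    nxt <- setdiff(unlist(adj[frontier]), seen)
    seen <- c(seen, nxt)
    tips <- c(tips, nxt[nxt <= ntip])
    frontier <- nxt
  }
  sort(tips)
}

.canon_key <- function(side, universe, min_tip) {
  if (!min_tip %in% side) side <- setdiff(universe, side)
  paste(sort(side), collapse = "|")
}

## Least-squares attachment of a taxon with distance vector d (ordered like
## pp$tips) to the edges of the pruned tree; returns the best edge index.
.ls_attach <- function(pp, d) {
  nedge <- nrow(pp$edges)
  np <- length(pp$tips)
  ssq <- numeric(nedge)
  for (e in seq_len(nedge)) {
    u <- pp$edges[e, 1]; v <- pp$edges[e, 2]; l <- pp$elen[e]
    inV <- pp$side_v[[e]]
    a <- pp$nd[u, seq_len(np)]
    b <- pp$nd[v, seq_len(np)]
    alpha <- if (any(!inV)) mean(d[!inV] - a[!inV]) else NA_real_
    beta <- if (any(inV)) mean(d[inV] - b[inV]) else NA_real_
    if (is.na(alpha)) alpha <- beta + l
    if (is.na(beta)) beta <- alpha + l
    x <- min(max((alpha - beta + l) / 2, 0), l)
    pend <- max((alpha + beta - l) / 2, 0)
    pred <- ifelse(inV, pend + (l - x) + b, pend + x + a)
    ssq[e] <- sum((d - pred)^2)
  }
  which.min(ssq)
}
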