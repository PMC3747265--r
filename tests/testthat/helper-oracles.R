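## Independent oracles used by the unit and acceptance tests. These are
## deliberately naive re-implementations (brute force / graph search /
## textbook formulas) kept separate from the package's own code paths.

## --- degenerate matching: expand the primer into all concrete variants and
## substring-scan both strands ------------------------------------------------
oracle_iupac_match <- function(primer_seq, target, max_mismatches = 0L) {
  variants_f <- expand_iupac(primer_seq)
  variants_r <- expand_iupac(revcomp_iupac(primer_seq))
  m <- nchar(primer_seq)
  tchars <- strsplit(target, "", fixed = TRUE)[[1]]
  L <- length(tchars)
  hits <- list()
  if (L >= m) {
    for (p in 0:(L - m)) {
      win <- paste(tchars[(p + 1):(p + m)], collapse = "")
      wchars <- tchars[(p + 1):(p + m)]
      mm_f <- min(vapply(strsplit(variants_f, "", fixed = TRUE),
                         function(v) sum(v != wchars | !wchars %in% c("A", "C", "G", "T")), 0L))
      mm_r <- min(vapply(strsplit(variants_r, "", fixed = TRUE),
                         function(v) sum(v != wchars | !wchars %in% c("A", "C", "G", "T")), 0L))
      if (mm_f <= max_mismatches) {
        hits[[length(hits) + 1L]] <- data.frame(start = p, strand = "+", mismatches = mm_f)
      }
      if (mm_r <= max_mismatches) {
        hits[[length(hits) + 1L]] <- data.frame(start = p, strand = "-", mismatches = mm_r)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(), strand = character(), mismatches = integer()))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## --- patristic distances: shortest paths on the weighted tree graph --------
oracle_patristic <- function(tree) {
  g <- igraph::graph_from_edgelist(apply(tree$edge, 2L, as.character), directed = FALSE)
  igraph::E(g)$weight <- tree$edge.length
  ntip <- length(tree$tip.label)
  d <- igraph::distances(g, v = as.character(seq_len(ntip)),
                         to = as.character(seq_len(ntip)))
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d[tree$tip.label, tree$tip.label]
}

## --- bipartitions: enumerate by splitting the tree at each internal edge ---
oracle_splits <- function(tree) {
  tr <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  ntip <- length(tr$tip.label)
  g <- igraph::graph_from_edgelist(apply(tr$edge, 2L, as.character), directed = FALSE)
  keys <- character(0)
  for (e in seq_len(nrow(tr$edge))) {
    a <- tr$edge[e, 1]; b <- tr$edge[e, 2]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, as.character(c(a, b))))
    comp <- igraph::components(g2)$membership
    side <- as.integer(names(comp)[comp == comp[as.character(b)]])
    side <- side[side <= ntip]
    if (length(side) <= 1L || length(side) >= ntip - 1L) next
    labs <- tr$tip.label[side]
    if (!min(tr$tip.label) %in% labs) labs <- setdiff(tr$tip.label, labs)
    keys <- c(keys, paste(sort(labs), collapse = "|"))
  }
  unique(keys)
}

oracle_rf <- function(t1, t2) {
  k1 <- oracle_splits(t1); k2 <- oracle_splits(t2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

## --- average-linkage clustering: recompute every cross-pair mean at every
## merge from the original matrix --------------------------------------------
oracle_average_linkage <- function(dm, cutoff) {
  ids <- rownames(dm)
  clusters <- as.list(ids)
  repeat {
    k <- length(clusters)
    if (k == 1L) break
    best <- NULL
    best_d <- Inf
    best_key <- NULL
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        d <- mean(dm[clusters[[i]], clusters[[j]]])
        key <- paste(sort(c(min(clusters[[i]]), min(clusters[[j]]))), collapse = "\r")
        if (d < best_d - 1e-15 ||
            (abs(d - best_d) <= 1e-12 && (is.null(best_key) || key < best_key))) {
          best_d <- d; best <- c(i, j); best_key <- key
        }
      }
    }
    if (best_d > cutoff) break
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  reps <- vapply(clusters, min, "")
  ord <- order(reps)
  out <- integer(length(ids)); names(out) <- ids
  for (k in seq_along(ord)) out[clusters[[ord[k]]]] <- k
  out
}

## --- textbook two-pass Pearson correlation ---------------------------------
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

## --- random trees / matrices ------------------------------------------------
random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE)
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  tr
}

random_support_tree <- function(n, seed) {
  tr <- random_tree(n, seed)
  set.seed(seed + 10000L)
  tr$node.label <- formatC(round(runif(tr$Nnode), 3), format = "g")
  tr
}

random_dist <- function(n, seed, scale = 1) {
  set.seed(seed)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2) * scale
  m <- m + t(m)
  dimnames(m) <- list(sprintf("s%02d", 1:n), sprintf("s%02d", 1:n))
  m
}
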