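## Perfect-character ("additive") libraries: every edge of the tree flips its
## own private set of alignment columns, so the p-distance between two leaves
## times the alignment length equals the number of columns flipped on their
## connecting path. Distances are exactly additive on the tree with edge
## length = flipped columns / total columns — a construction-free oracle for
## distance-based inference.
make_additive_library <- function(tree, cols_per_unit = 1L, pad = 0L) {
  rooted <- if (ape::is.rooted(tree)) tree else
    ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
  ne <- nrow(rooted$edge)
  ## integer column counts per edge
  k <- pmax(round(rooted$edge.length * cols_per_unit), 0L)
  Ltot <- sum(k) + pad
  offs <- cumsum(c(0L, k))[seq_len(ne)]
  n <- length(rooted$tip.label)
  nn <- n + rooted$Nnode
  state <- matrix(FALSE, nrow = nn, ncol = Ltot)
  parent <- integer(nn)
  parent[rooted$edge[, 2]] <- rooted$edge[, 1]
  ## fill preorder
  ord <- order(ape::node.depth(rooted)[rooted$edge[, 2]], decreasing = TRUE)
  for (e in ord) {
    child <- rooted$edge[e, 2]
    s <- state[rooted$edge[e, 1], ]
    if (k[e] > 0L) {
      idx <- (offs[e] + 1L):(offs[e] + k[e])
      s[idx] <- !s[idx]
    }
    state[child, ] <- s
  }
  seqs <- apply(state[seq_len(n), , drop = FALSE], 1L, function(b) {
    paste(ifelse(b, "C", "A"), collapse = "")
  })
  names(seqs) <- rooted$tip.label
  list(library = seq_library(seqs),
       edge_length_unit = 1 / Ltot,
       tree = rooted)
}

## Small deterministic aligned library with planted site, for primer tests.
toy_library <- function() {
  seqs <- c(
    a = "AAC-GGATTAGATACCCTGAAA",
    b = "AACCGGATTAGATACCCTG--A",
    c = "AACCGGATTAGATACCCTGCCA",
    d = "TTTTTTTTTTTTTTTTTTTTTA"
  )
  tax <- parse_lineages(names(seqs),
                        c("Bacteria;P1;C1;O1;F1;G1", "Bacteria;P1;C1;O1;F1;G1",
                          "Bacteria;P2;C2;O2;F2;G2", "Bacteria;P2;C2;O2;F2;G3"))
  seq_library(seqs, tax)
}
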