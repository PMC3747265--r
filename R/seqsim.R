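#' Default 16S-like region map
#'
#' Ten conserved blocks (relative substitution rate 0.25) alternating with
#' nine faster-evolving variable blocks (relative rate 4.0), laid out to the
#' approximate E. coli coordinates of the V1-V9 regions over 1542 alignment
#' columns. The five built-in primer sites are planted inside the conserved
#' blocks at their E. coli positions; each site serves the forward and the
#' reverse primer of its pair.
#'
#' @param conserved_rate relative substitution rate inside conserved blocks
#' @param variable_rate relative substitution rate inside variable blocks
#' @return a `region_map`: data frame (kind, start, end, rate) with an
#'   attribute `plants` describing planted primer sites
#' @export
default_region_map <- function(conserved_rate = 0.25, variable_rate = 4.0) {
  ## [start, end] 1-based inclusive alignment columns, E. coli-like layout
  v <- rbind(c(69, 99), c(137, 242), c(433, 497), c(576, 682), c(822, 879),
             c(986, 1043), c(1117, 1173), c(1243, 1294), c(1435, 1465))
  bounds <- c(1, as.vector(t(cbind(v[, 1], v[, 2] + 1L))), 1543)
  starts <- bounds[-length(bounds)]
  ends <- c(bounds[-1] - 1L)
  kind <- rep(c("conserved", "variable"), length.out = length(starts))
  df <- data.frame(kind = kind, start = as.integer(starts), end = as.integer(ends),
                   rate = ifelse(kind == "conserved", conserved_rate, variable_rate))
  plants <- do.call(rbind, lapply(.BASE_PRIMERS, function(b) {
    data.frame(name = paste0(b$pos, substr(b$dir, 1, 1)), seq = b$seq,
               direction = b$dir, start = b$site[1], end = b$site[2],
               stringsAsFactors = FALSE)
  }))
  region_map(df, plants)
}

#' Construct/validate a region map
#'
#' @param blocks data frame with columns kind ("conserved"/"variable"),
#'   start, end (1-based inclusive columns), rate (>= 0)
#' @param plants optional data frame (name, seq, direction, start, end)
#'   of primer sites planted verbatim into the root sequence; reverse-direction
#'   primers are planted as their reverse complement (the sense-strand site)
#' @return a `region_map`
#' @export
region_map <- function(blocks, plants = NULL) {
  stopifnot(all(c("kind", "start", "end", "rate") %in% names(blocks)))
  if (any(blocks$rate < 0)) stop("block rates must be >= 0")
  o <- order(blocks$start)
  blocks <- blocks[o, , drop = FALSE]
  if (blocks$start[1] != 1L) stop("region map must start at column 1")
  if (any(blocks$start[-1] != blocks$end[-nrow(blocks)] + 1L)) {
    stop("region map blocks must tile the alignment without gaps")
  }
  if (!is.null(plants)) {
    L <- max(blocks$end)
    for (i in seq_len(nrow(plants))) {
      p <- plants[i, ]
      if (p$end - p$start + 1L != nchar(p$seq)) {
        stop("config error: planted site span does not match primer length for ", p$name)
      }
      blk <- which(blocks$start <= p$start & blocks$end >= p$end)
      if (length(blk) != 1L || blocks$kind[blk] != "conserved") {
        stop("config error: planted primer ", p$name,
             " does not fit inside a single conserved block")
      }
      if (p$end > L) stop("config error: planted primer beyond alignment end")
    }
  }
  structure(blocks, plants = plants, class = c("region_map", "data.frame"))
}

#' Per-column relative substitution rates implied by a region map
#' @param rmap a `region_map`
#' @return numeric vector over alignment columns
#' @export
region_rates <- function(rmap) {
  rates <- numeric(max(rmap$end))
  for (i in seq_len(nrow(rmap))) rates[rmap$start[i]:rmap$end[i]] <- rmap$rate[i]
  rates
}

#' Simulation configuration
#'
#' Defaults describe the stand-in for a database-wide reference library:
#' a 50-taxon random tree whose depth keeps the conserved primer sites
#' nearly intact (as real universal primer sites are) while variable regions
#' accumulate roughly ten-fold more substitutions.
#'
#' @param n_taxa number of leaves (>= 3)
#' @param seed integer seed fixing all randomness end-to-end
#' @param tree_model "yule" (random splits, gamma-distributed branch
#'   lengths) or "coalescent"
#' @param mean_branch_length expected substitutions per site per edge at
#'   relative rate 1
#' @param region_map a [region_map()]
#' @param taxonomy_depth ranks labelled by clade membership
#' @return a `sim_config` list
#' @export
sim_config <- function(n_taxa = 50L, seed = 1L,
                       tree_model = c("yule", "coalescent"),
                       mean_branch_length = 0.00075,
                       region_map = default_region_map(),
                       taxonomy_depth = c("phylum", "class", "order", "family", "genus")) {
  tree_model <- match.arg(tree_model)
  if (n_taxa < 3L) stop("value error: n_taxa must be >= 3")
  if (mean_branch_length <= 0) stop("value error: mean branch length must be > 0")
  structure(list(n_taxa = as.integer(n_taxa), seed = as.integer(seed),
                 tree_model = tree_model,
                 mean_branch_length = mean_branch_length,
                 region_map = region_map,
                 taxonomy_depth = taxonomy_depth),
            class = "sim_config")
}

#' Simulate a random binary tree
#'
#' @param config a [sim_config()]
#' @return an unrooted binary `ape::phylo` with `config$n_taxa` leaves
#'   (labelled t001, t002, ...); the rooted form used for sequence evolution
#'   is kept in attribute `rooted`
#' @export
simulate_tree <- function(config) {
  if (config$n_taxa < 3L) stop("value error: n_taxa must be >= 3")
  rooted <- with_seed(derive_seed(config$seed, "tree"), {
    tr <- if (config$tree_model == "coalescent") {
      ape::rcoal(config$n_taxa)
    } else {
      ape::rtree(config$n_taxa, rooted = TRUE, br = NULL)
    }
    ne <- nrow(tr$edge)
    if (config$tree_model == "coalescent") {
      tr$edge.length <- tr$edge.length * (config$mean_branch_length * ne /
                                            sum(tr$edge.length))
    } else {
      ## gamma(shape 2) keeps the requested mean but avoids the mass of
      ## near-zero internal edges an exponential would produce, which no
      ## finite alignment could resolve
      tr$edge.length <- stats::rgamma(ne, shape = 2,
                                      rate = 2 / config$mean_branch_length)
    }
    tr$tip.label <- sprintf("t%03d", seq_len(config$n_taxa))
    tr
  })
  out <- ape::unroot(rooted)
  attr(out, "rooted") <- rooted
  out
}

#' Evolve an aligned library along a tree
#'
#' Jukes-Cantor substitution kernel with per-column rate multipliers from the
#' region map; no indels. The root sequence is drawn uniformly at random,
#' then any planted primer sites are written into it verbatim (degenerate
#' positions resolved to one concrete base, uniformly at random; reverse
#' primers are planted as the reverse complement, i.e. the sense-strand
#' site). Taxonomy is assigned afterwards by [clade_taxonomy()] when
#' requested.
#'
#' @param tree a rooted or unrooted `ape::phylo` with branch lengths (if
#'   unrooted, the `rooted` attribute from [simulate_tree()] is used when
#'   present, otherwise the tree is rooted at its first internal node)
#' @param rmap a [region_map()]
#' @param seed integer seed
#' @param gap_fraction optional fraction of cells replaced by gaps (I/O
#'   testing aid; default 0 keeps the alignment trivial)
#' @return a [seq_library()]
#' @export
evolve_alignment <- function(tree, rmap, seed = 1L, gap_fraction = 0) {
  rooted <- attr(tree, "rooted")
  if (is.null(rooted)) {
    rooted <- if (ape::is.rooted(tree)) tree else
      ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
  }
  if (is.null(rooted$edge.length)) stop("tree must have branch lengths")
  rates <- region_rates(rmap)
  L <- length(rates)
  n <- length(rooted$tip.label)
  root_node <- n + 1L
  plants <- attr(rmap, "plants")

  with_seed(derive_seed(seed, "evolve"), {
    root_seq <- sample.int(4L, L, replace = TRUE)  # 1..4 = A,C,G,T
    if (!is.null(plants)) {
      for (i in seq_len(nrow(plants))) {
        p <- plants[i, ]
        site <- if (p$direction == "forward") p$seq else revcomp_iupac(p$seq)
        concrete <- vapply(iupac_masks(site), function(mask) {
          opts <- which(bitwAnd(mask, c(1L, 2L, 4L, 8L)) > 0L)
          opts[sample.int(length(opts), 1L)]
        }, 0L)
        root_seq[p$start:p$end] <- concrete
      }
    }
    nodes_total <- n + rooted$Nnode
    seqs <- matrix(0L, nrow = nodes_total, ncol = L)
    seqs[root_node, ] <- root_seq
    ## preorder edge traversal
    ord <- order(rooted$edge[, 1])
    edges <- rooted$edge[ord, , drop = FALSE]
    elen <- rooted$edge.length[ord]
    ## ensure parents are processed before children: reorder by DFS
    dfs <- integer(0)
    stack <- root_node
    children <- split(seq_len(nrow(edges)), edges[, 1])
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      kid_edges <- children[[as.character(v)]]
      if (!is.null(kid_edges)) {
        dfs <- c(dfs, kid_edges)
        stack <- c(stack, edges[kid_edges, 2])
      }
    }
    for (ei in dfs) {
      par <- edges[ei, 1]; child <- edges[ei, 2]
      lambda <- rates * elen[ei]
      p_change <- 0.75 * (1 - exp(-4 / 3 * lambda))
      s <- seqs[par, ]
      mut <- which(stats::runif(L) < p_change)
      if (length(mut)) {
        ## conditional on change, the three other bases are equally likely
        shift <- sample.int(3L, length(mut), replace = TRUE)
        s[mut] <- ((s[mut] - 1L + shift) %% 4L) + 1L
      }
      seqs[child, ] <- s
    }
    chars <- c("A", "C", "G", "T")
    tip_seqs <- vapply(seq_len(n), function(i) paste(chars[seqs[i, ]], collapse = ""), "")
    names(tip_seqs) <- rooted$tip.label
    if (gap_fraction > 0) {
      for (i in seq_len(n)) {
        v <- strsplit(tip_seqs[[i]], "", fixed = TRUE)[[1]]
        idx <- which(stats::runif(L) < gap_fraction)
        v[idx] <- "-"
        tip_seqs[[i]] <- paste(v, collapse = "")
      }
    }
    seq_library(tip_seqs)
  })
}

#' Clade-derived taxonomy labels
#'
#' Cuts the rooted tree at increasing depth thresholds (fractions of the
#' median root-to-tip distance); the maximal clades hanging below each
#' threshold define nested groups labelled per rank, so every label induces
#' a connected subtree. The domain is constant ("Bacteria").
#'
#' @param tree rooted `ape::phylo` (or a tree carrying the `rooted`
#'   attribute from [simulate_tree()])
#' @param ranks ranks below domain to label
#' @param fractions depth thresholds per rank, as fractions of the median
#'   tip depth
#' @return taxonomy data frame (id + rank columns)
#' @export
clade_taxonomy <- function(tree,
                           ranks = c("phylum", "class", "order", "family", "genus"),
                           fractions = NULL) {
  rooted <- attr(tree, "rooted")
  if (is.null(rooted)) rooted <- tree
  if (!ape::is.rooted(rooted)) stop("clade taxonomy needs a rooted tree")
  if (is.null(fractions)) {
    fractions <- seq(0.2, 0.8, length.out = length(ranks))
  }
  stopifnot(length(fractions) == length(ranks))
  n <- length(rooted$tip.label)
  depth <- ape::node.depth.edgelength(rooted)
  med_tip <- stats::median(depth[seq_len(n)])
  ## path of ancestors for each tip (root first)
  anc <- .ancestor_paths(rooted)
  tax <- data.frame(id = rooted$tip.label, domain = "Bacteria",
                    stringsAsFactors = FALSE)
  for (k in seq_along(ranks)) {
    h <- fractions[k] * med_tip
    grp <- vapply(seq_len(n), function(tip) {
      path <- c(anc[[tip]], tip)  # root .. tip
      hit <- path[depth[path] >= h]
      if (length(hit)) hit[1] else tip
    }, 0L)
    labels <- sprintf("%s%02d", substr(ranks[k], 1, 1), match(grp, sort(unique(grp))))
    tax[[ranks[k]]] <- labels
  }
  tax
}

.ancestor_paths <- function(rooted) {
  n <- length(rooted$tip.label)
  root <- n + 1L
  parent <- integer(n + rooted$Nnode)
  parent[rooted$edge[, 2]] <- rooted$edge[, 1]
  lapply(seq_len(n), function(tip) {
    path <- integer(0)
    v <- tip
    while (v != root) {
      v <- parent[v]
      path <- c(v, path)
    }
    path
  })
}

#' Simulate a full 16S-like evaluation input
#'
#' Convenience wrapper: tree + evolved alignment + clade taxonomy, all
#' driven by one seed.
#'
#' @param config a [sim_config()]
#' @return list with elements `tree` (unrooted, with `rooted` attribute),
#'   `library` (a `seq_library` with taxonomy), and `config`
#' @export
simulate_library <- function(config = sim_config()) {
  tree <- simulate_tree(config)
  lib <- evolve_alignment(tree, config$region_map, seed = config$seed)
  tax <- clade_taxonomy(tree, ranks = config$taxonomy_depth)
  lib <- seq_library(lib$seqs, tax)
  list(tree = tree, library = lib, config = config)
}

#' Simulate a genus-structured training library
#'
#' Draws independent random ancestor sequences (one per genus, pairwise
#' p-distance around 0.75, hence well above any realistic inter-genus
#' threshold) and derives each member by independent per-site mutation, so
#' intra-genus p-distances stay near `2 * intra_rate`. Lineages above genus
#' are assigned by grouping genera into phyla.
#'
#' @param n_genera number of genera
#' @param n_per_genus sequences per genus
#' @param seq_length ungapped sequence length
#' @param intra_rate per-site mutation probability from ancestor to member
#' @param n_phyla number of phyla the genera are spread over
#' @param seed integer seed
#' @return a [seq_library()] with taxonomy
#' @export
simulate_genus_library <- function(n_genera = 10L, n_per_genus = 5L,
                                   seq_length = 800L, intra_rate = 0.005,
                                   n_phyla = 3L, seed = 1L) {
  chars <- c("A", "C", "G", "T")
  with_seed(derive_seed(seed, "genus-library"), {
    seqs <- character(0)
    lineages <- character(0)
    for (g in seq_len(n_genera)) {
      anc <- sample.int(4L, seq_length, replace = TRUE)
      phy <- ((g - 1L) %% n_phyla) + 1L
      for (m in seq_len(n_per_genus)) {
        s <- anc
        mut <- which(stats::runif(seq_length) < intra_rate)
        if (length(mut)) {
          s[mut] <- ((s[mut] - 1L + sample.int(3L, length(mut), replace = TRUE)) %% 4L) + 1L
        }
        id <- sprintf("g%02d_s%02d", g, m)
        seqs[id] <- paste(chars[s], collapse = "")
        lineages[id] <- sprintf("Bacteria;phy%02d;cls%02d;ord%02d;fam%02d;gen%02d",
                                phy, g, g, g, g)
      }
    }
    seq_library(seqs, parse_lineages(names(seqs), unname(lineages)))
  })
}
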