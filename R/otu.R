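#' Average-linkage OTU clustering with a hard cutoff
#'
#' Agglomerative clustering in which the distance between clusters is the
#' arithmetic mean of all cross-pair distances ("average neighbor" / UPGMA
#' linkage). Merging stops as soon as the minimum inter-cluster distance
#' exceeds the cutoff, i.e. the dendrogram is cut at exactly the cutoff
#' height. Deterministic: ties are broken on the lexicographically smallest
#' (label, label) pair, labels being each cluster's smallest member id.
#'
#' @param dm distance matrix
#' @param cutoff non-negative merge-height cutoff
#' @return named integer vector id -> cluster, clusters numbered by their
#'   smallest member id's sort order
#' @export
average_linkage_otus <- function(dm, cutoff) {
  check_distance_matrix(dm)
  if (cutoff < 0) stop("value error: cutoff must be >= 0")
  ids <- rownames(dm)
  n <- length(ids)
  members <- as.list(ids)
  sizes <- rep(1L, n)
  D <- dm
  active_label <- ids
  while (length(members) > 1L) {
    na <- nrow(D)
    Dm <- D
    diag(Dm) <- Inf
    mn <- min(Dm)
    if (mn > cutoff) break
    cand <- which(Dm - mn <= 1e-12 * max(1, mn), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    ck <- apply(cand, 1L, function(idx) {
      paste(sort(c(active_label[idx[1]], active_label[idx[2]])), collapse = "\r")
    })
    pick <- cand[order(ck)[1], ]
    i <- pick[1]; j <- pick[2]
    ## Lance-Williams update for average linkage
    keep <- setdiff(seq_len(na), c(i, j))
    dnew <- (sizes[i] * D[i, keep] + sizes[j] * D[j, keep]) / (sizes[i] + sizes[j])
    newmem <- c(members[[i]], members[[j]])
    newlab <- min(active_label[i], active_label[j])
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew), c(dnew, 0))
    members <- c(members[keep], list(newmem))
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
    active_label <- c(active_label[keep], newlab)
  }
  ## number clusters by sorted smallest-member label
  reps <- vapply(members, min, "")
  ord <- order(reps)
  out <- integer(n)
  names(out) <- ids
  for (k in seq_along(ord)) out[members[[ord[k]]]] <- k
  out
}

#' OTU richness of a library at given cutoffs
#' @param library aligned [seq_library()]
#' @param cutoffs numeric vector of clustering cutoffs
#' @param model distance model ("p" default, matching common OTU pipelines)
#' @return named integer vector of OTU counts per cutoff
#' @export
otu_richness <- function(library, cutoffs = c(0.01, 0.02, 0.03), model = "p") {
  dm <- pairwise_seq_distance(library, model = model)
  vapply(stats::setNames(cutoffs, fmt_num(cutoffs)), function(ct) {
    max(average_linkage_otus(dm, ct))
  }, 0L)
}

#' Short-read vs full-length OTU richness ratios
#'
#' Clusters both libraries at each cutoff and reports the ratio of short-read
#' to full-length OTU counts; values below 1 mean the reads under-resolve
#' the richness the full gene supports.
#'
#' @param sr_library short-read [seq_library()]
#' @param nfl_library full-length [seq_library()]
#' @param cutoffs non-empty numeric vector of cutoffs
#' @param model distance model
#' @return data frame: cutoff, otus_sr, otus_nfl, ratio
#' @export
richness_ratio <- function(sr_library, nfl_library,
                           cutoffs = c(0.01, 0.02, 0.03), model = "p") {
  if (length(cutoffs) == 0L) stop("value error: empty cutoff list")
  sr <- otu_richness(sr_library, cutoffs, model)
  nfl <- otu_richness(nfl_library, cutoffs, model)
  data.frame(cutoff = cutoffs, otus_sr = as.integer(sr),
             otus_nfl = as.integer(nfl), ratio = as.numeric(sr) / as.numeric(nfl))
}
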