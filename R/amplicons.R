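#' Extract in-silico short reads (amplicons) around a primer site
#'
#' Per sequence the primer is located on its ungapped bases (on the strand
#' implied by the primer's direction, allowing `anchor_mismatches`
#' mismatches). The read window spans `read_length` ungapped bases: for a
#' forward primer it starts at the primer's 5' start and extends 3'-ward; for
#' a reverse primer it ends at the primer site's 3'-most reference position
#' and extends 5'-ward. The primer-covered bases are then removed, so a full
#' read retains `read_length - primer_length` bases. Reads are reported in
#' reference (sense) orientation as the alignment columns covering the
#' retained bases; the union of retained columns defines one shared column
#' space, with positions outside a given read gap-filled.
#'
#' @param library aligned [seq_library()]
#' @param primer a [primer_spec()]
#' @param read_length ungapped window size in bases (default 280)
#' @param anchor_mismatches mismatch tolerance when locating the site
#'   (default 2; coverage statistics use a strict 0 instead)
#' @param on_missing "exclude" drops sequences without an anchor (logged);
#'   "majority-column" trims them at the library-majority column window
#' @return a `seq_library` of aligned short reads; attribute `read_info` is a
#'   data frame (id, anchored, truncated, start, end) with ungapped 0-based
#'   half-open retained coordinates
#' @export
extract_amplicons <- function(library, primer, read_length = 280L,
                              anchor_mismatches = 2L,
                              on_missing = c("exclude", "majority-column")) {
  on_missing <- match.arg(on_missing)
  plen <- nchar(primer$iupac_seq)
  if (read_length <= plen) stop("value error: read_length must exceed primer length")
  strand <- if (primer$direction == "forward") "+" else "-"
  ids <- names(library$seqs)
  n <- length(ids)
  gapchar <- c("-", ".")
  col_maps <- lapply(library$seqs, function(s) {
    which(!strsplit(s, "", fixed = TRUE)[[1]] %in% gapchar)
  })
  ungapped <- vapply(library$seqs, degap, "")

  windows <- vector("list", n)          # ungapped [start, end) retained per seq
  truncated <- logical(n)
  anchored <- logical(n)
  for (i in seq_len(n)) {
    hits <- iupac_match(primer, ungapped[[i]], max_mismatches = anchor_mismatches,
                        strands = strand)
    if (nrow(hits) == 0L) next
    anchored[i] <- TRUE
    s <- hits$start[which.min(hits$mismatches)[1]]
    ## prefer the best anchor; among equal mismatch counts take the leftmost
    s <- hits$start[order(hits$mismatches, hits$start)][1]
    L <- nchar(ungapped[[i]])
    if (primer$direction == "forward") {
      lo <- s + plen
      hi <- s + read_length
      if (hi > L) { hi <- L; truncated[i] <- TRUE }
    } else {
      e <- s + plen
      lo <- e - read_length
      hi <- s
      if (lo < 0L) { lo <- 0L; truncated[i] <- TRUE }
    }
    if (hi <= lo) { anchored[i] <- FALSE; next }
    windows[[i]] <- c(lo, hi)
  }

  if (!any(anchored)) stop("no sequence could be anchored for primer ", primer$name)
  if (any(!anchored)) {
    pe_log("info", "primer %s: %d/%d sequences lack an anchor (%s)",
           primer$name, sum(!anchored), n, on_missing)
  }

  ## alignment columns retained per sequence
  col_sets <- vector("list", n)
  for (i in seq_len(n)) {
    if (anchored[i]) {
      w <- windows[[i]]
      col_sets[[i]] <- col_maps[[i]][(w[1] + 1L):w[2]]
    }
  }
  if (on_missing == "majority-column" && any(!anchored)) {
    starts <- vapply(col_sets[anchored], min, 0L)
    ends <- vapply(col_sets[anchored], max, 0L)
    maj_start <- as.integer(names(sort(table(starts), decreasing = TRUE))[1])
    maj_end <- as.integer(names(sort(table(ends), decreasing = TRUE))[1])
    for (i in which(!anchored)) {
      keep <- col_maps[[i]][col_maps[[i]] >= maj_start & col_maps[[i]] <= maj_end]
      if (length(keep)) col_sets[[i]] <- keep
    }
  }

  keep_seq <- !vapply(col_sets, is.null, logical(1))
  use_cols <- sort(unique(unlist(col_sets[keep_seq])))
  mat <- matrix("-", nrow = sum(keep_seq), ncol = length(use_cols),
                dimnames = list(ids[keep_seq], NULL))
  full <- seq_matrix(library)
  for (i in which(keep_seq)) {
    sel <- match(col_sets[[i]], use_cols)
    mat[ids[i], sel] <- full[ids[i], col_sets[[i]]]
  }
  out_seqs <- apply(mat, 1L, paste, collapse = "")
  tax <- library$taxonomy
  if (!is.null(tax)) tax <- tax[tax$id %in% names(out_seqs), , drop = FALSE]
  out <- seq_library(out_seqs, tax)
  attr(out, "read_info") <- data.frame(
    id = ids,
    anchored = anchored,
    truncated = truncated,
    start = vapply(windows, function(w) if (is.null(w)) NA_integer_ else as.integer(w[1]), 0L),
    end = vapply(windows, function(w) if (is.null(w)) NA_integer_ else as.integer(w[2]), 0L),
    stringsAsFactors = FALSE
  )
  attr(out, "primer") <- primer
  out
}
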