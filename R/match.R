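#' Match a degenerate primer against an ungapped sequence
#'
#' A hit at (0-based) position `p` on strand `+` means that at every primer
#' position the primer's IUPAC set contains the target base, with at most
#' `max_mismatches` violations; strand `-` reports the same for the primer's
#' reverse complement, with the position giving the leftmost base of the
#' matched window in target coordinates. Ambiguous target bases (including
#' `N`) match nothing and consume mismatch budget.
#'
#' @param primer a [primer_spec()] or an IUPAC string
#' @param seq ungapped target sequence (a string)
#' @param max_mismatches non-negative integer, smaller than the primer length
#' @param strands which strands to scan ("both", "+", "-")
#' @return data frame with columns `start` (0-based), `strand`, `mismatches`
#' @export
iupac_match <- function(primer, seq, max_mismatches = 0L, strands = c("both", "+", "-")) {
  strands <- match.arg(strands)
  pseq <- if (inherits(primer, "primer_spec")) primer$iupac_seq else toupper(primer)
  m <- nchar(pseq)
  if (max_mismatches < 0L || max_mismatches >= m) {
    stop("max_mismatches must be in [0, primer length)")
  }
  if (grepl("[-.]", seq)) stop("target sequence must be ungapped")
  tm <- iupac_masks(seq, target = TRUE)
  hits <- list()
  if (strands %in% c("both", "+")) {
    hits[["+"]] <- .scan_masks(iupac_masks(pseq), tm, max_mismatches)
  }
  if (strands %in% c("both", "-")) {
    hits[["-"]] <- .scan_masks(iupac_masks(revcomp_iupac(pseq)), tm, max_mismatches)
  }
  out <- do.call(rbind, lapply(names(hits), function(s) {
    h <- hits[[s]]
    if (is.null(h) || nrow(h) == 0L) return(NULL)
    data.frame(start = h$start, strand = s, mismatches = h$mismatches,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(start = integer(), strand = character(), mismatches = integer())
  } else {
    out <- out[order(out$start, out$strand), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

## Sliding comparison of primer masks against target masks; returns 0-based
## starts and mismatch counts.
.scan_masks <- function(pm, tm, max_mismatches) {
  m <- length(pm)
  L <- length(tm)
  if (L < m) return(data.frame(start = integer(), mismatches = integer()))
  n_off <- L - m + 1L
  mism <- integer(n_off)
  idx <- seq_len(n_off)
  for (j in seq_len(m)) {
    mism <- mism + as.integer(bitwAnd(pm[j], tm[idx + j - 1L]) == 0L)
  }
  keep <- which(mism <= max_mismatches)
  data.frame(start = keep - 1L, mismatches = mism[keep])
}

#' Primer coverage and non-coverage table
#'
#' A sequence counts as covered iff the primer (or its reverse complement)
#' matches its ungapped sequence with zero mismatches. With a `group_rank`
#' other than "all", per-group rows are emitted alongside a total row per
#' primer (group "all").
#'
#' @param primers list of [primer_spec()] (or a single spec)
#' @param library a [seq_library()]
#' @param group_rank "all" or one of the taxonomy ranks present in the library
#' @param max_mismatches mismatch budget (the classical probe-matching run
#'   uses 0)
#' @return data frame: primer, group, covered, total, coverage, noncoverage
#' @export
coverage <- function(primers, library, group_rank = "all", max_mismatches = 0L) {
  if (inherits(primers, "primer_spec")) primers <- list(primers)
  if (length(library) == 0L) stop("value error: empty library")
  if (!identical(group_rank, "all")) {
    if (is.null(library$taxonomy) || !group_rank %in% names(library$taxonomy)) {
      stop("config error: unknown rank '", group_rank, "'")
    }
  }
  ungapped <- vapply(library$seqs, degap, "")
  rows <- list()
  for (p in primers) {
    hit <- vapply(ungapped, function(s) {
      nrow(iupac_match(p, s, max_mismatches = max_mismatches)) > 0L
    }, logical(1))
    add_row <- function(group, mask) {
      tot <- sum(mask)
      cov <- sum(hit[mask])
      data.frame(primer = p$name, group = group, covered = cov, total = tot,
                 coverage = 100 * cov / tot,
                 noncoverage = 100 - 100 * cov / tot,
                 stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- add_row("all", rep(TRUE, length(hit)))
    if (!identical(group_rank, "all")) {
      groups <- library$taxonomy[[group_rank]]
      for (g in sort(unique(stats::na.omit(groups)))) {
        rows[[length(rows) + 1L]] <- add_row(g, !is.na(groups) & groups == g)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
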