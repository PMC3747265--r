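#' Construct an aligned sequence library
#'
#' A `seq_library` holds aligned, gapped sequences (uppercase, gaps as `-`)
#' keyed by unique ids, with an optional ranked taxonomy table. `U` is
#' normalized to `T` and `.` gaps to `-` on construction.
#'
#' @param seqs named character vector of aligned sequences
#' @param taxonomy optional data frame with column `id` plus rank columns
#'   (`domain`, `phylum`, `class`, `order`, `family`, `genus`)
#' @return object of class `seq_library`
#' @export
seq_library <- function(seqs, taxonomy = NULL) {
  if (length(seqs) == 0L) stop("library must contain at least one sequence")
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) stop("every sequence needs a non-empty id")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(seqs)
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("alignment error: sequences have unequal aligned lengths (",
         paste(sort(unique(lens)), collapse = ", "), ")")
  }
  if (any(nchar(degap(seqs)) == 0L)) stop("gap-only sequence in library")
  if (!is.null(taxonomy)) {
    if (!"id" %in% names(taxonomy)) stop("taxonomy needs an 'id' column")
    if (!all(ids %in% taxonomy$id)) {
      pe_log("warn", "taxonomy missing for %d sequence(s)",
             sum(!ids %in% taxonomy$id))
    }
    taxonomy <- taxonomy[match(ids, taxonomy$id), , drop = FALSE]
    taxonomy$id <- ids
    rownames(taxonomy) <- NULL
  }
  structure(list(seqs = seqs, taxonomy = taxonomy), class = "seq_library")
}

#' @export
print.seq_library <- function(x, ...) {
  cat(sprintf("seq_library: %d sequences, alignment length %d%s\n",
              length(x$seqs), nchar(x$seqs[[1]]),
              if (is.null(x$taxonomy)) "" else ", with taxonomy"))
  invisible(x)
}

#' @export
length.seq_library <- function(x) length(x$seqs)

#' Alignment length of a library
#' @param lib a `seq_library`
#' @return integer number of alignment columns
#' @export
alignment_length <- function(lib) nchar(lib$seqs[[1]])

#' Library as a character matrix (rows = sequences, columns = sites)
#' @param lib a `seq_library`
#' @return character matrix with sequence ids as rownames
#' @export
seq_matrix <- function(lib) {
  m <- do.call(rbind, strsplit(unname(lib$seqs), "", fixed = TRUE))
  rownames(m) <- names(lib$seqs)
  m
}

#' Subset a library by sequence ids
#' @param lib a `seq_library`
#' @param ids character vector of ids to keep
#' @return a `seq_library`
#' @export
subset_library <- function(lib, ids) {
  miss <- setdiff(ids, names(lib$seqs))
  if (length(miss)) stop("unknown ids: ", paste(miss, collapse = ", "))
  tax <- lib$taxonomy
  if (!is.null(tax)) tax <- tax[tax$id %in% ids, , drop = FALSE]
  seq_library(lib$seqs[ids], tax)
}

.TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

#' Parse semicolon-delimited lineage strings into a rank table
#'
#' Ranks are fixed as domain;phylum;class;order;family;genus. Shorter
#' lineages are right-padded with `NA`.
#'
#' @param ids sequence ids
#' @param lineages character vector of semicolon-separated lineage strings
#' @return data frame with `id` plus the six rank columns
#' @export
parse_lineages <- function(ids, lineages) {
  parts <- strsplit(lineages, ";", fixed = TRUE)
  m <- t(vapply(parts, function(p) {
    p <- trimws(p)
    length(p) <- length(.TAX_RANKS)
    p
  }, character(length(.TAX_RANKS))))
  colnames(m) <- .TAX_RANKS
  cbind(data.frame(id = ids, stringsAsFactors = FALSE),
        as.data.frame(m, stringsAsFactors = FALSE))
}

#' Collapse a rank table back into lineage strings
#' @param taxonomy data frame as produced by [parse_lineages()]
#' @return named character vector of `;`-joined lineages
#' @export
format_lineages <- function(taxonomy) {
  m <- as.matrix(taxonomy[, .TAX_RANKS, drop = FALSE])
  m[is.na(m)] <- ""
  out <- apply(m, 1L, function(r) paste(r[nzchar(r) | seq_along(r) <= max(which(nzchar(r)), 1L)], collapse = ";"))
  stats::setNames(sub(";+$", "", out), taxonomy$id)
}
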