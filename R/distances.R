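#' Pairwise sequence distances (p or Jukes-Cantor)
#'
#' p-distance: mismatches over compared columns; columns with a gap or an
#' ambiguous base in either sequence are skipped (pairwise deletion). The JC
#' correction is `-(3/4) * log(1 - 4p/3)`, undefined at p >= 0.75
#' (saturation): by default that raises an error, or can be capped at the
#' distance implied by `p = 0.749`.
#'
#' @param library aligned [seq_library()] with at least 2 sequences
#' @param model "p" or "jc"
#' @param on_saturation "error" or "cap" (jc only)
#' @param columns optional column subset (window) to restrict to
#' @return symmetric numeric matrix with zero diagonal, ids as dimnames
#' @export
pairwise_seq_distance <- function(library, model = c("p", "jc"),
                                  on_saturation = c("error", "cap"),
                                  columns = NULL) {
  model <- match.arg(model)
  on_saturation <- match.arg(on_saturation)
  if (length(library) < 2L) stop("value error: need at least 2 sequences")
  m <- seq_matrix(library)
  if (!is.null(columns)) m <- m[, columns, drop = FALSE]
  codes <- match(m, c("A", "C", "G", "T"))
  dim(codes) <- dim(m)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    xi <- codes[i, ]
    for (j in (i + 1L):n) {
      xj <- codes[j, ]
      ok <- !is.na(xi) & !is.na(xj)
      ncomp <- sum(ok)
      if (ncomp == 0L) stop("value error: zero comparable columns for pair ",
                            rownames(m)[i], "/", rownames(m)[j])
      p <- sum(xi[ok] != xj[ok]) / ncomp
      if (model == "jc") {
        if (p >= 0.75) {
          if (on_saturation == "error") {
            stop("saturation error: p >= 0.75 for pair ", rownames(m)[i], "/",
                 rownames(m)[j])
          }
          p <- 0.749
        }
        p <- -0.75 * log(1 - 4 * p / 3)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Validate a distance matrix
#' @param dm numeric matrix
#' @return `dm`, invisibly, after checks
#' @export
check_distance_matrix <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) stop("value error: not a square matrix")
  if (is.null(rownames(dm)) || anyDuplicated(rownames(dm))) {
    stop("value error: distance matrix needs unique ids")
  }
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-12, check.attributes = FALSE))) {
    stop("value error: asymmetric distance matrix")
  }
  if (any(diag(dm) != 0)) stop("value error: nonzero diagonal")
  if (any(dm < 0)) stop("value error: negative distances")
  invisible(dm)
}

#' Normalize a distance matrix to a maximum of one
#' @param dm distance matrix
#' @return `dm / max(dm)`
#' @export
normalize_max1 <- function(dm) {
  mx <- max(dm)
  if (mx <= 0) stop("value error: all-zero matrix cannot be normalized")
  dm / mx
}

#' Write a distance matrix as TSV (ids in first row and column)
#' @param dm distance matrix
#' @param path output path
#' @return `path`, invisibly
#' @export
write_distance_tsv <- function(dm, path) {
  df <- data.frame(id = rownames(dm), dm, check.names = FALSE)
  write_report_tsv(df, path)
}

#' Read a distance matrix TSV written by [write_distance_tsv()]
#' @param path TSV path
#' @return numeric matrix
#' @export
read_distance_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  check_distance_matrix(m)
  m
}
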