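#' Construct a degenerate primer specification
#'
#' @param name primer name (position + direction convention, e.g. "518f")
#' @param iupac_seq primer sequence 5'->3' over IUPAC codes
#' @param direction "forward" or "reverse"
#' @param reference_position optional integer c(start, end) on a reference
#'   gene coordinate system (1-based, sense strand)
#' @return object of class `primer_spec`
#' @export
primer_spec <- function(name, iupac_seq,
                        direction = c("forward", "reverse"),
                        reference_position = NULL) {
  direction <- match.arg(direction)
  if (!nzchar(name)) stop("primer name must be non-empty")
  iupac_seq <- toupper(iupac_seq)
  iupac_masks(iupac_seq)  # validates characters
  if (!is.null(reference_position)) {
    stopifnot(length(reference_position) == 2L, reference_position[1] <= reference_position[2])
  }
  structure(list(name = name, iupac_seq = iupac_seq, direction = direction,
                 reference_position = reference_position),
            class = "primer_spec")
}

#' @export
print.primer_spec <- function(x, ...) {
  cat(sprintf("primer %s (%s): %s [%d nt]\n", x$name, x$direction,
              x$iupac_seq, nchar(x$iupac_seq)))
  invisible(x)
}

## The ten classical universal 16S primers evaluated by this package: five
## published sequences plus their reverse complements, so each conserved
## stretch is probed in both sequencing directions. Reference positions are
## E. coli 16S coordinates of the sense-strand site.
.BASE_PRIMERS <- list(
  list(pos = "338",  seq = "GCTGCCTCCCGTAGGAGT",  dir = "reverse", site = c(338L, 355L)),
  list(pos = "518",  seq = "ATTACCGCGGCTGCTGG",   dir = "reverse", site = c(526L, 542L)),
  list(pos = "799",  seq = "AACMGGATTAGATACCCKG", dir = "forward", site = c(781L, 799L)),
  list(pos = "926",  seq = "AACTCAAAGGAATTGACGG", dir = "forward", site = c(908L, 926L)),
  list(pos = "1062", seq = "CTCACRRCACGAGCTGAC",  dir = "reverse", site = c(1064L, 1081L))
)

#' The built-in set of ten universal 16S primers
#'
#' Five published primer sequences (338r, 518r, 799f, 926f, 1062r) and their
#' reverse complements (338f, 518f, 799r, 926r, 1062f), giving a
#' forward/reverse pair per conserved site.
#'
#' @return named list of [primer_spec()] objects
#' @export
builtin_primers <- function() {
  out <- list()
  for (b in .BASE_PRIMERS) {
    fwd_seq <- if (b$dir == "forward") b$seq else revcomp_iupac(b$seq)
    rev_seq <- if (b$dir == "reverse") b$seq else revcomp_iupac(b$seq)
    out[[paste0(b$pos, "f")]] <-
      primer_spec(paste0(b$pos, "f"), fwd_seq, "forward", b$site)
    out[[paste0(b$pos, "r")]] <-
      primer_spec(paste0(b$pos, "r"), rev_seq, "reverse", b$site)
  }
  out
}

#' Write a primer set as TSV (name, sequence, direction)
#' @param primers list of `primer_spec`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_primer_table <- function(primers, path) {
  df <- data.frame(name = vapply(primers, `[[`, "", "name"),
                   sequence = vapply(primers, `[[`, "", "iupac_seq"),
                   direction = vapply(primers, `[[`, "", "direction"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
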