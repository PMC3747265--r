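## IUPAC nucleotide codes as 4-bit masks (A=1, C=2, G=4, T=8).
.IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

## Mask for target bases: only concrete A/C/G/T can satisfy a primer
## position; any ambiguity in the target (including N) matches nothing and
## therefore consumes mismatch budget.
.TARGET_MASK <- c(A = 1L, C = 2L, G = 4L, T = 8L)

iupac_masks <- function(seq, target = FALSE) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  if (target) {
    m <- .TARGET_MASK[ch]
    m[is.na(m)] <- 0L
  } else {
    m <- .IUPAC_MASK[ch]
    if (anyNA(m)) {
      stop("non-IUPAC character in primer sequence: ",
           paste(unique(ch[is.na(m)]), collapse = ", "))
    }
  }
  unname(m)
}

## Complement of a 4-bit base mask: swap A<->T and C<->G bits.
.comp_mask <- function(m) {
  bitwOr(bitwOr(bitwShiftL(bitwAnd(m, 1L), 3L), bitwShiftL(bitwAnd(m, 2L), 1L)),
         bitwOr(bitwShiftR(bitwAnd(m, 4L), 1L), bitwShiftR(bitwAnd(m, 8L), 3L)))
}

.MASK_TO_CODE <- {
  x <- character(16)
  x[.IUPAC_MASK + 1L] <- names(.IUPAC_MASK)
  x
}

#' Reverse complement of an IUPAC (possibly degenerate) sequence
#'
#' @param seq character scalar over IUPAC nucleotide codes
#' @return reverse complement, uppercase
#' @export
revcomp_iupac <- function(seq) {
  m <- iupac_masks(seq)
  paste(rev(.MASK_TO_CODE[.comp_mask(m) + 1L]), collapse = "")
}

## Expand a degenerate sequence into all concrete A/C/G/T variants.
## Exported because tests and the coverage oracle rely on it; cheap for the
## primer lengths in actual use.
#' Expand a degenerate IUPAC sequence into concrete variants
#'
#' @param seq IUPAC sequence
#' @return character vector of all concrete (A/C/G/T-only) realizations
#' @export
expand_iupac <- function(seq) {
  m <- iupac_masks(seq)
  sets <- lapply(m, function(mask) {
    names(.TARGET_MASK)[bitwAnd(mask, .TARGET_MASK) > 0L]
  })
  grid <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  apply(grid[, rev(seq_along(sets)), drop = FALSE], 1L, paste, collapse = "")
}

#' Remove alignment gaps from a sequence
#'
#' @param seq character scalar; `-` and `.` are treated as gaps
#' @return ungapped sequence
#' @export
degap <- function(seq) gsub("[-.]", "", seq)
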