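#' @keywords internal
"_PACKAGE"

## Logging goes to stderr so TSV reports on stdout stay clean.
.pe_log_level <- new.env(parent = emptyenv())
.pe_log_level$threshold <- 2L  # 1 = debug, 2 = info, 3 = warn, 4 = error

#' Set the logging threshold
#'
#' @param level one of "debug", "info", "warn", "error"
#' @return previous level, invisibly
#' @export
pe_log_level <- function(level = c("info", "debug", "warn", "error")) {
  level <- match.arg(level)
  old <- .pe_log_level$threshold
  .pe_log_level$threshold <- match(level, c("debug", "info", "warn", "error"))
  invisible(c("debug", "info", "warn", "error")[old])
}

pe_log <- function(level, fmt, ...) {
  lv <- match(level, c("debug", "info", "warn", "error"))
  if (lv >= .pe_log_level$threshold) {
    message(sprintf("[%s] %s", toupper(level), sprintf(fmt, ...)))
  }
  invisible(NULL)
}

#' Derive a stage-specific child seed from a master seed
#'
#' Stable string hash combined with the master seed, kept inside the 32-bit
#' integer range so it can be passed to [set.seed()].
#'
#' @param master integer master seed
#' @param stage character stage name
#' @return integer seed in \[1, 2^31 - 2\]
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  p <- 2147483647
  h <- 0
  for (c in utf8ToInt(paste(stage, collapse = "/"))) h <- (h * 31 + c) %% p
  as.integer((h + (as.double(master) %% p) * 7919) %% (p - 1) + 1)
}

## local RNG scope: run code with a given seed without clobbering the caller's
## RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  code
}

## Deterministic numeric formatting used by all TSV writers.
fmt_num <- function(x, digits = 12) {
  ifelse(is.na(x), "NA", formatC(x, format = "g", digits = digits))
}

#' Write a data frame as a TSV report
#'
#' @param df data frame
#' @param path output path
#' @param digits significant digits for numeric columns
#' @return `path`, invisibly
#' @export
write_report_tsv <- function(df, path, digits = 12) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) out[[j]] <- fmt_num(out[[j]], digits)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
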