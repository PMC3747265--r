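#' Read an aligned FASTA file into a sequence library
#'
#' All records must share one alignment length; `U` is stored as `T` and `.`
#' as `-`. Duplicate ids are a format error.
#'
#' @param path FASTA file path
#' @param taxonomy_path optional TSV with columns `id` and `lineage`
#'   (semicolon-ranked) and no header, or a header line `id<TAB>lineage`
#' @return a [seq_library()]
#' @export
read_fasta <- function(path, taxonomy_path = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  seqs <- as.character(ss)
  ## ids = first whitespace-delimited token of the header
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(names(seqs))) {
    stop("format error: duplicate ids in ", path)
  }
  tax <- if (!is.null(taxonomy_path)) read_taxonomy(taxonomy_path) else NULL
  seq_library(seqs, tax)
}

#' Write a library as aligned FASTA (plus optional taxonomy TSV)
#'
#' @param lib a `seq_library`
#' @param path output FASTA path
#' @param taxonomy_path optional path for the lineage TSV
#' @return `path`, invisibly
#' @export
write_fasta <- function(lib, path, taxonomy_path = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(lib$seqs)) {
    writeLines(c(paste0(">", id), lib$seqs[[id]]), con)
  }
  if (!is.null(taxonomy_path) && !is.null(lib$taxonomy)) {
    lin <- format_lineages(lib$taxonomy)
    utils::write.table(data.frame(id = names(lin), lineage = unname(lin)),
                       taxonomy_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a taxonomy TSV (id, semicolon-ranked lineage)
#' @param path TSV path; a header row `id  lineage` is tolerated
#' @return rank table as from [parse_lineages()]
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                          stringsAsFactors = FALSE, col.names = c("id", "lineage"))
  if (nrow(df) && identical(tolower(df$id[1]), "id")) df <- df[-1L, , drop = FALSE]
  parse_lineages(df$id, df$lineage)
}

#' Read a Newick tree with branch supports
#'
#' Two support dialects are understood: numeric internal-node labels
#' (`(A:1,B:2)90:0.5`) and bracketed branch comments (`(A:1,B:2):0.5[90]`).
#' With `support_dialect = "auto"` the bracket form is used when present,
#' otherwise numeric node labels are taken as supports. If any parsed support
#' exceeds 1 the whole tree is assumed to be on a 0-100 scale and divided by
#' 100, so downstream weighted Robinson-Foulds arithmetic always sees
#' supports in \[0, 1\].
#'
#' @param path Newick file path
#' @param support_dialect one of "auto", "internal-node-label", "branch-comment"
#' @return an [ape::phylo] tree; supports live in `node.label` as numbers in
#'   \[0, 1\] (empty string where absent)
#' @export
read_newick <- function(path,
                        support_dialect = c("auto", "internal-node-label", "branch-comment")) {
  support_dialect <- match.arg(support_dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close) stop("parse error: unbalanced parentheses in ", path)
  has_comment <- grepl("\\[[0-9.eE+-]+\\]", txt)
  use_comment <- (support_dialect == "branch-comment") ||
    (support_dialect == "auto" && has_comment)
  if (use_comment) {
    ## move ":len[support]" after a ')' into a node label: ")support:len"
    txt <- gsub("\\)\\s*:\\s*([0-9.eE+-]+)\\s*\\[\\s*([0-9.eE+-]+)\\s*\\]",
                ")\\2:\\1", txt)
    ## strip any remaining comments (e.g. on tip branches)
    txt <- gsub("\\[[^]]*\\]", "", txt)
  }
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) stop("parse error: ", conditionMessage(e)))
  if (is.null(tr)) stop("parse error: could not read a tree from ", path)
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0)) {
    stop("value error: negative branch length in ", path)
  }
  normalize_supports(tr)
}

## Rescale numeric node labels to [0,1]; non-numeric labels are left alone
## but then do not act as supports.
normalize_supports <- function(tree) {
  if (is.null(tree$node.label)) return(tree)
  sup <- suppressWarnings(as.numeric(tree$node.label))
  if (all(is.na(sup))) return(tree)
  if (any(sup > 1, na.rm = TRUE)) sup <- sup / 100
  if (any(sup < 0 | sup > 1, na.rm = TRUE)) {
    stop("value error: supports outside [0, 1] after rescaling")
  }
  lbl <- ifelse(is.na(sup), "", fmt_num(sup))
  tree$node.label <- lbl
  tree
}

#' Numeric supports of a tree's internal nodes
#' @param tree an `ape::phylo`
#' @param default value used where a node has no numeric label
#' @return numeric vector of length `tree$Nnode`
#' @export
tree_supports <- function(tree, default = NA_real_) {
  if (is.null(tree$node.label)) return(rep(default, tree$Nnode))
  sup <- suppressWarnings(as.numeric(tree$node.label))
  sup[is.na(sup)] <- default
  sup
}

#' Write a tree in Newick format (supports as internal node labels)
#' @param tree an `ape::phylo`
#' @param path output path
#' @param digits significant digits for branch lengths
#' @return `path`, invisibly
#' @export
write_newick <- function(tree, path, digits = 15) {
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

#' Read a primer table (TSV: name, sequence, direction)
#' @param path TSV path, with or without a header line
#' @return list of [primer_spec()] objects
#' @export
read_primer_table <- function(path) {
  if (!file.exists(path)) stop("config error: no such primer file: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                          stringsAsFactors = FALSE,
                          col.names = c("name", "sequence", "direction"))
  if (nrow(df) && identical(tolower(df$name[1]), "name")) df <- df[-1L, , drop = FALSE]
  if (anyDuplicated(df$name)) stop("duplicate primer names in ", path)
  lapply(seq_len(nrow(df)), function(i) {
    primer_spec(df$name[i], df$sequence[i], df$direction[i])
  })
}

#' Read an INI-style key=value run configuration
#'
#' Section headers `[name]` are allowed and ignored; keys are global.
#' Comment lines start with `#` or `;`.
#'
#' @param path config file path
#' @return named character vector of settings
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config error: no such config file: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !grepl("^[#;\\[]", lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stop("config error: malformed line(s): ", paste(lines[bad], collapse = " | "))
  stats::setNames(trimws(vapply(kv, `[`, "", 3L)), trimws(vapply(kv, `[`, "", 2L)))
}
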