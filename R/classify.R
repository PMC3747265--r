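## k-mer ids: base-4 integer encoding of A/C/G/T words; words touching any
## other character are skipped.
.seq_words <- function(seq, k) {
  codes <- match(strsplit(toupper(degap(seq)), "", fixed = TRUE)[[1]],
                 c("A", "C", "G", "T")) - 1L
  if (length(codes) < k) return(integer(0))
  emb <- stats::embed(codes, k)           # row i = codes[i+k-1 .. i]
  ok <- rowSums(is.na(emb)) == 0L
  if (!any(ok)) return(integer(0))
  unique(as.integer(emb[ok, , drop = FALSE] %*% 4^(seq_len(k) - 1L)))
}

#' Train a Wang-style naive-Bayes k-mer classifier
#'
#' Word prior over N reference sequences: `P_i = (n(w_i) + 0.5) / (N + 1)`,
#' with `n(w_i)` the number of sequences containing word `w_i`. Genus
#' conditional over the M sequences of genus G:
#' `P(w_i | G) = (m(w_i) + P_i) / (M + 1)`. Both counts are per-sequence
#' presence counts, and the prior acts as the smoothing floor for words a
#' genus has never seen.
#'
#' @param reference_library [seq_library()] whose taxonomy reaches genus
#' @param k word length (default 8)
#' @return object of class `nb_classifier`
#' @export
train <- function(reference_library, k = 8L) {
  tax <- reference_library$taxonomy
  if (is.null(tax) || !"genus" %in% names(tax)) {
    stop("value error: reference library must carry genus labels")
  }
  if (anyNA(tax$genus)) stop("value error: missing genus label(s)")
  seqs <- reference_library$seqs
  words <- lapply(seqs, function(s) {
    w <- .seq_words(s, k)
    if (!length(w)) pe_log("warn", "sequence shorter than k; skipped")
    w
  })
  keep <- lengths(words) > 0L
  words <- words[keep]
  genus <- tax$genus[match(names(words), tax$id)]
  N <- length(words)
  vocab <- sort(unique(unlist(words)))
  widx <- lapply(words, function(w) match(w, vocab))
  n_w <- tabulate(unlist(widx), nbins = length(vocab))
  prior <- (n_w + 0.5) / (N + 1)
  genera <- sort(unique(genus))
  m <- matrix(0L, nrow = length(genera), ncol = length(vocab),
              dimnames = list(genera, NULL))
  M <- stats::setNames(integer(length(genera)), genera)
  for (i in seq_len(N)) {
    g <- genus[i]
    m[g, widx[[i]]] <- m[g, widx[[i]]] + 1L
    M[g] <- M[g] + 1L
  }
  ## one lineage per genus
  lin_cols <- intersect(.TAX_RANKS, names(tax))
  lineage <- unique(tax[tax$id %in% names(words), lin_cols, drop = FALSE])
  lineage <- lineage[match(genera, lineage$genus), , drop = FALSE]
  if (anyDuplicated(lineage$genus) || anyNA(lineage$genus)) {
    stop("value error: each genus must map to exactly one lineage")
  }
  rownames(lineage) <- NULL
  structure(list(k = as.integer(k), vocab = vocab, prior = prior,
                 m = m, M = M, N = N, genera = genera, lineage = lineage),
            class = "nb_classifier")
}

#' @export
print.nb_classifier <- function(x, ...) {
  cat(sprintf("naive-Bayes k-mer classifier: k=%d, %d genera, %d reference sequences, %d words\n",
              x$k, length(x$genera), x$N, length(x$vocab)))
  invisible(x)
}

.CLASSIFY_RANKS <- c("phylum", "class", "order", "family", "genus")

#' Classify a query sequence with bootstrap confidence
#'
#' Genus scores are sums of log conditionals over the query's distinct
#' in-vocabulary words. Per bootstrap round, `floor(W/8)` of the W distinct
#' words are resampled with replacement and the winning genus recorded; the
#' confidence of each rank is the percentage of rounds whose winner shares
#' the full-set winner's label at that rank. Labels below the cutoff are
#' reported as "unclassified". Reverse-orientation reads should be
#' reverse-complemented to sense orientation first (`orient = "reverse"`
#' does this).
#'
#' @param model an `nb_classifier`
#' @param query sequence string (gaps are removed)
#' @param n_bootstrap bootstrap rounds (default 100)
#' @param cutoff confidence cutoff in percent (default 80)
#' @param seed integer seed for the resampling
#' @param orient "sense" (as is) or "reverse" (reverse-complement first)
#' @return data frame: rank, label, confidence
#' @export
classify <- function(model, query, n_bootstrap = 100L, cutoff = 80,
                     seed = 1L, orient = c("sense", "reverse")) {
  orient <- match.arg(orient)
  if (orient == "reverse") query <- revcomp_iupac(degap(query))
  w <- .seq_words(query, model$k)
  idx <- match(w, model$vocab)
  idx <- idx[!is.na(idx)]
  ranks <- .CLASSIFY_RANKS
  if (length(idx) == 0L) {
    return(data.frame(rank = ranks, label = "unclassified", confidence = 0,
                      stringsAsFactors = FALSE))
  }
  ## G x W log-conditional matrix for this query's words
  logcond <- log(sweep(model$m[, idx, drop = FALSE], 2L, model$prior[idx], "+"))
  logcond <- sweep(logcond, 1L, log(model$M + 1), "-")
  full_score <- rowSums(logcond)
  winner <- model$genera[order(-full_score, model$genera)][1]
  nW <- max(1L, length(idx) %/% 8L)
  win_rounds <- with_seed(derive_seed(seed, "classify-bootstrap"), {
    vapply(seq_len(n_bootstrap), function(b) {
      sel <- sample.int(length(idx), nW, replace = TRUE)
      sc <- rowSums(logcond[, sel, drop = FALSE])
      model$genera[order(-sc, model$genera)][1]
    }, "")
  })
  lin_w <- model$lineage[model$lineage$genus == winner, , drop = FALSE]
  lin_rounds <- model$lineage[match(win_rounds, model$lineage$genus), , drop = FALSE]
  out <- data.frame(rank = ranks, label = NA_character_, confidence = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(ranks)) {
    rk <- ranks[i]
    lab <- if (rk %in% names(lin_w)) lin_w[[rk]][1] else NA_character_
    conf <- if (is.na(lab)) 0 else 100 * mean(lin_rounds[[rk]] == lab, na.rm = FALSE)
    out$label[i] <- if (!is.na(lab) && conf >= cutoff) lab else "unclassified"
    out$confidence[i] <- conf
  }
  out
}

#' Classify every sequence of a library
#' @param model an `nb_classifier`
#' @param library a [seq_library()]
#' @param ... passed to [classify()] (`n_bootstrap`, `cutoff`, `orient`)
#' @param seed integer; per-sequence seeds are derived from it
#' @return data frame: id, rank, label, confidence
#' @export
classify_library <- function(model, library, seed = 1L, ...) {
  res <- lapply(names(library$seqs), function(id) {
    r <- classify(model, library$seqs[[id]], seed = derive_seed(seed, id), ...)
    cbind(data.frame(id = id, stringsAsFactors = FALSE), r)
  })
  do.call(rbind, res)
}

#' Score short-read against full-length taxonomic assignments
#'
#' Implements the standard performance bookkeeping: correct assignments by
#' read including/excluding reads whose full-length (reference) sequence was
#' itself unclassified; false positives (classified in SR, unclassified in
#' NFL); total unclassified SR reads; false negatives (classified in NFL,
#' unclassified in SR); and unclassified reference reads. By the inclusive
#' convention a read unclassified in both libraries counts as an agreement
#' (switchable).
#'
#' @param sr_results data frame (id, rank, label) for the short reads
#' @param nfl_results same for the full-length reference assignments
#' @param rank rank at which to score (e.g. "phylum" or "genus")
#' @param both_unclassified_agree logical; the inclusive-tally convention
#' @return one-row data frame of percentages
#' @export
score_assignments <- function(sr_results, nfl_results, rank,
                              both_unclassified_agree = TRUE) {
  sr <- sr_results[sr_results$rank == rank, ]
  nfl <- nfl_results[nfl_results$rank == rank, ]
  if (!setequal(sr$id, nfl$id)) stop("value error: read id mismatch")
  ids <- sort(sr$id)
  s <- sr$label[match(ids, sr$id)]
  f <- nfl$label[match(ids, nfl$id)]
  n <- length(ids)
  s_un <- s == "unclassified"
  f_un <- f == "unclassified"
  agree <- (s == f) & !(s_un & f_un)
  if (both_unclassified_agree) agree <- agree | (s_un & f_un)
  correct_incl <- 100 * sum(agree) / n
  correct_excl <- if (any(!f_un)) 100 * sum((s == f)[!f_un]) / sum(!f_un) else NA_real_
  data.frame(
    rank = rank,
    correct_incl = correct_incl,
    correct_excl = correct_excl,
    false_positive = 100 * sum(!s_un & f_un) / n,
    unclassified_total = 100 * sum(s_un) / n,
    false_negative = 100 * sum(s_un & !f_un) / n,
    unclassified_ref = 100 * sum(f_un) / n,
    stringsAsFactors = FALSE
  )
}
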