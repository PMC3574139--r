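FEATURE_BLOCKS <- c("unigram", "bigram", "trigram", "med_term", "sem_type")

# contiguous n-grams of a token vector, space-joined
ngrams_of <- function(tokens, n) {
  k <- length(tokens) - n + 1L
  if (k <= 0L) return(character(0))
  if (n == 1L) return(tokens)
  parts <- lapply(seq_len(n), function(j) tokens[j:(j + k - 1L)])
  do.call(paste, parts)
}

#' Build the feature vocabulary
#'
#' Five disjoint feature blocks: content-token unigrams, bigrams and trigrams
#' (the keyword-based block, F1) plus matched medical terms and the closed
#' semantic-type list (the medical domain-specific block, F2). An n-gram
#' enters the vocabulary when it occurs in at least `min_df` distinct
#' messages; medical terms are all matched lexicon terms; the semantic-type
#' block is always the full packaged list of 20 types. Column order is
#' deterministic: blocks in the order unigram, bigram, trigram, med_term,
#' sem_type, lexicographic within block.
#'
#' @param tokenized list of tokenized messages.
#' @param matches match tibble from [match_corpus()].
#' @param min_df minimum number of distinct messages an n-gram must occur in
#'   (default 3).
#' @return object of class `vocabulary`: list with per-block term vectors,
#'   `column_index` (named integer vector feature -> column), `block` (block
#'   of each column) and `min_df`.
#' @export
build_vocabulary <- function(tokenized, matches, min_df = 3L) {
  min_df <- as.integer(min_df)
  if (min_df < 1L) stop("min_df must be >= 1")
  if (length(tokenized) == 0) stop("cannot build a vocabulary from zero messages")
  ngram_block <- function(n) {
    per_msg <- lapply(tokenized, function(tm) {
      unique(ngrams_of(tm$content_tokens, n))
    })
    df <- table(unlist(per_msg))
    sort(as.character(names(df[df >= min_df])))
  }
  unigrams <- ngram_block(1L)
  bigrams <- ngram_block(2L)
  trigrams <- ngram_block(3L)
  med_terms <- sort(unique(matches$term))
  sem_types <- semantic_types()$abbrev
  # columns carry a block prefix: the same string may legitimately appear in
  # both the unigram and the medical-term block as two distinct features
  feats <- c(paste0("unigram:", unigrams, recycle0 = TRUE),
             paste0("bigram:", bigrams, recycle0 = TRUE),
             paste0("trigram:", trigrams, recycle0 = TRUE),
             paste0("med_term:", med_terms, recycle0 = TRUE),
             paste0("sem_type:", sem_types, recycle0 = TRUE))
  block <- rep(FEATURE_BLOCKS,
               times = c(length(unigrams), length(bigrams), length(trigrams),
                         length(med_terms), length(sem_types)))
  structure(list(unigrams = unigrams, bigrams = bigrams, trigrams = trigrams,
                 med_terms = med_terms, sem_types = sem_types,
                 column_index = setNames(seq_along(feats), feats),
                 block = block, min_df = min_df),
            class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf(paste0("<vocabulary> %d unigrams, %d bigrams, %d trigrams, ",
                     "%d medical terms, %d semantic types (min_df = %d)\n"),
              length(x$unigrams), length(x$bigrams), length(x$trigrams),
              length(x$med_terms), length(x$sem_types), x$min_df))
  invisible(x)
}

#' Vectorize messages into the message-by-feature count matrix
#'
#' n-gram cells hold raw occurrence counts per message; medical-term cells
#' hold match counts; the cell for semantic type `t` holds the total count of
#' matches whose type set contains `t` (a term carrying two types increments
#' two columns). Row order equals input order.
#'
#' @param tokenized list of tokenized messages.
#' @param matches match tibble from [match_corpus()].
#' @param vocabulary a [build_vocabulary()] result.
#' @return object of class `feature_matrix`: list with `values` (integer
#'   matrix, rows = messages, columns = features), `row_ids`, `vocabulary`.
#' @export
vectorize <- function(tokenized, matches, vocabulary) {
  stopifnot(inherits(vocabulary, "vocabulary"))
  ids <- vapply(tokenized, `[[`, character(1), "message_id")
  if (nrow(matches) > 0 && !all(matches$message_id %in% ids)) {
    stop("matches reference message id(s) absent from the tokenized input")
  }
  nfeat <- length(vocabulary$column_index)
  n <- length(tokenized)
  # one pass: collect (row, column) codes for every feature occurrence, then
  # tabulate them into the dense count matrix in a single call
  gram_lists <- lapply(tokenized, function(tm) {
    toks <- tm$content_tokens
    c(paste0("unigram:", ngrams_of(toks, 1L), recycle0 = TRUE),
      paste0("bigram:", ngrams_of(toks, 2L), recycle0 = TRUE),
      paste0("trigram:", ngrams_of(toks, 3L), recycle0 = TRUE))
  })
  row_all <- rep.int(seq_len(n), lengths(gram_lists))
  col_all <- vocabulary$column_index[unlist(gram_lists, use.names = FALSE)]
  if (nrow(matches) > 0) {
    mrow <- match(matches$message_id, ids)
    mcol <- vocabulary$column_index[paste0("med_term:", matches$term)]
    trow <- rep.int(mrow, lengths(matches$types))
    tcol <- vocabulary$column_index[paste0("sem_type:",
                                           unlist(matches$types,
                                                  use.names = FALSE))]
    row_all <- c(row_all, mrow, trow)
    col_all <- c(col_all, mcol, tcol)
  }
  ok <- !is.na(col_all)
  code <- (col_all[ok] - 1) * n + row_all[ok]
  M <- matrix(tabulate(code, nbins = as.double(n) * nfeat), nrow = n,
              dimnames = list(ids, names(vocabulary$column_index)))
  storage.mode(M) <- "integer"
  structure(list(values = M, row_ids = ids, vocabulary = vocabulary),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d message(s) x %d feature(s)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Select feature blocks
#'
#' Column-slices a feature matrix to a subset of the five blocks, preserving
#' row order. The shorthand `"F1"` expands to the keyword-based blocks
#' (unigram, bigram, trigram) and `"F2"` to the medical domain-specific
#' blocks (med_term, sem_type).
#'
#' @param matrix a [vectorize()] result.
#' @param blocks character subset of
#'   `c("unigram","bigram","trigram","med_term","sem_type")`, or the
#'   shorthands `"F1"`, `"F2"`.
#' @return a `feature_matrix` restricted to the requested blocks.
#' @export
select_blocks <- function(matrix, blocks) {
  stopifnot(inherits(matrix, "feature_matrix"))
  blocks <- unique(unlist(lapply(blocks, function(b) {
    switch(b, F1 = c("unigram", "bigram", "trigram"),
           F2 = c("med_term", "sem_type"), b)
  })))
  bad <- setdiff(blocks, FEATURE_BLOCKS)
  if (length(bad) > 0) stop("unknown feature block(s): ",
                            paste(bad, collapse = ", "))
  if (length(blocks) == 0) stop("block set must be non-empty")
  voc <- matrix$vocabulary
  keep <- voc$block %in% blocks
  voc2 <- voc
  if (!"unigram" %in% blocks) voc2$unigrams <- character(0)
  if (!"bigram" %in% blocks) voc2$bigrams <- character(0)
  if (!"trigram" %in% blocks) voc2$trigrams <- character(0)
  if (!"med_term" %in% blocks) voc2$med_terms <- character(0)
  if (!"sem_type" %in% blocks) voc2$sem_types <- character(0)
  feats <- names(voc$column_index)[keep]
  voc2$column_index <- setNames(seq_along(feats), feats)
  voc2$block <- voc$block[keep]
  structure(list(values = matrix$values[, keep, drop = FALSE],
                 row_ids = matrix$row_ids, vocabulary = voc2),
            class = "feature_matrix")
}

#' Export a feature matrix as sparse text + vocabulary JSON
#'
#' Writes a MatrixMarket coordinate file of the nonzero counts and a sidecar
#' JSON describing the vocabulary, for inspection and cross-language reuse.
#'
#' @param matrix a `feature_matrix`.
#' @param mtx_path,vocab_path output paths.
#' @export
export_feature_matrix <- function(matrix, mtx_path, vocab_path) {
  stopifnot(inherits(matrix, "feature_matrix"))
  M <- matrix$values
  nz <- which(M != 0, arr.ind = TRUE)
  con <- file(mtx_path, "w")
  on.exit(close(con))
  writeLines("%%MatrixMarket matrix coordinate integer general", con)
  writeLines(sprintf("%d %d %d", nrow(M), ncol(M), nrow(nz)), con)
  if (nrow(nz) > 0) {
    ord <- order(nz[, 2], nz[, 1])
    writeLines(sprintf("%d %d %d", nz[ord, 1], nz[ord, 2],
                       M[nz[ord, , drop = FALSE]]), con)
  }
  voc <- matrix$vocabulary
  jsonlite::write_json(
    list(row_ids = matrix$row_ids,
         features = names(voc$column_index),
         block = voc$block, min_df = voc$min_df),
    vocab_path, auto_unbox = TRUE)
  invisible(NULL)
}
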