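#' Semantic-type table
#'
#' The closed set of 20 coarse biomedical categories (UMLS-style semantic
#' types) used to type lexicon terms, e.g. `sosy` = Sign or Symptom, `phsu` =
#' Pharmacologic Substance. Packaged as `extdata/semantic_types.tsv`.
#'
#' @return tibble with columns `abbrev`, `name`, one row per type, in
#'   the packaged order.
#' @export
semantic_types <- function() {
  path <- system.file("extdata", "semantic_types.tsv", package = "medtopic",
                      mustWork = TRUE)
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   stringsAsFactors = FALSE)
  as_tibble(df)
}

#' Build a medical-term lexicon
#'
#' A dictionary of multiword medical terms, each mapped to one or more
#' semantic types — the stand-in for concept mapping against a full
#' biomedical metathesaurus. Terms are stored stemmed (same Porter stemmer
#' as message preprocessing) so that lexicon and messages normalize
#' identically; duplicate terms merge their type sets.
#'
#' @param terms character vector of terms (1-5 tokens each, unstemmed ok).
#' @param types list of character vectors of type abbreviations, parallel to
#'   `terms` (or a single vector recycled).
#' @param stem apply the Porter stemmer to term tokens (default TRUE).
#' @return object of class `lexicon`: list with `entries` (tibble: `term`,
#'   `types` list-column), `max_term_len`, and an internal hash index.
#' @export
lexicon <- function(terms, types, stem = TRUE) {
  terms <- tolower(as.character(terms))
  if (!is.list(types)) types <- rep(list(as.character(types)), length(terms))
  stopifnot(length(terms) == length(types))
  if (any(!nzchar(trimws(terms)))) stop("lexicon terms must be non-empty")
  known <- semantic_types()$abbrev
  for (i in seq_along(types)) {
    bad <- setdiff(types[[i]], known)
    if (length(bad) > 0) {
      stop(sprintf("unknown semantic type '%s' for term '%s'",
                   bad[1], terms[i]))
    }
    if (length(types[[i]]) == 0) {
      stop(sprintf("term '%s' has an empty type set", terms[i]))
    }
  }
  if (stem) {
    terms <- vapply(strsplit(terms, "\\s+"), function(tk) {
      paste(porter_stem(tk), collapse = " ")
    }, character(1))
  }
  # merge duplicates by type-set union, keeping first-appearance order
  uniq <- !duplicated(terms)
  merged <- lapply(terms[uniq], function(t) {
    sort(unique(unlist(types[terms == t])))
  })
  entries <- tibble(term = terms[uniq], types = merged)
  index <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(entries))) {
    assign(entries$term[i], entries$types[[i]], envir = index)
  }
  structure(list(entries = entries,
                 max_term_len = if (nrow(entries) == 0) 0L else
                   max(lengths(strsplit(entries$term, " "))),
                 index = index),
            class = "lexicon")
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("<lexicon> %d term(s), max term length %d token(s)\n",
              nrow(x$entries), x$max_term_len))
  invisible(x)
}

#' Load a lexicon from a TSV file
#'
#' Format: `term<TAB>type1|type2`, UTF-8, no header. Terms are lowercased and
#' stemmed on load; duplicate term lines merge by type-set union. Unknown
#' type abbreviations and empty terms are errors naming the offending line.
#'
#' @param path TSV file path.
#' @param stem apply the Porter stemmer to term tokens (default TRUE).
#' @return a [lexicon].
#' @export
load_lexicon <- function(path, stem = TRUE) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  terms <- character(length(keep))
  types <- vector("list", length(keep))
  known <- semantic_types()$abbrev
  for (i in seq_along(keep)) {
    ln <- keep[i]
    parts <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2 || !nzchar(trimws(parts[1]))) {
      stop(sprintf("lexicon line %d: expected 'term<TAB>types', got '%s'",
                   ln, lines[ln]))
    }
    ty <- strsplit(trimws(parts[2]), "|", fixed = TRUE)[[1]]
    ty <- trimws(ty[nzchar(trimws(ty))])
    bad <- setdiff(ty, known)
    if (length(bad) > 0) {
      stop(sprintf("lexicon line %d: unknown semantic type '%s'", ln, bad[1]))
    }
    if (length(ty) == 0) {
      stop(sprintf("lexicon line %d: empty type set", ln))
    }
    terms[i] <- trimws(parts[1])
    types[[i]] <- ty
  }
  lexicon(terms, types, stem = stem)
}

#' Packaged toy medical lexicon
#'
#' A small typed term dictionary built from the hot-topic vocabulary of
#' cancer and diabetes discussion boards (symptoms, complications,
#' examinations, procedures, drugs and related anatomy). It emulates, at toy
#' scale, concept extraction against a licensed biomedical metathesaurus,
#' which cannot be redistributed.
#'
#' @return a [lexicon].
#' @export
toy_lexicon <- function() {
  load_lexicon(system.file("extdata", "toy_lexicon.tsv", package = "medtopic",
                           mustWork = TRUE))
}

#' Match lexicon terms in a token sequence
#'
#' Greedy left-to-right longest-match scan over stemmed content tokens: at
#' each position the longest lexicon entry starting there (up to the
#' lexicon's maximum term length) is emitted and the scan advances past it,
#' so matches never overlap and appear in position order.
#'
#' @param tokens character vector of stemmed content tokens.
#' @param lex a [lexicon].
#' @param message_id optional id attached to each match.
#' @return tibble with columns `message_id`, `term`, `start` (0-based),
#'   `end` (exclusive), `types` (list-column).
#' @export
match_terms <- function(tokens, lex, message_id = NA_character_) {
  stopifnot(inherits(lex, "lexicon"))
  n <- length(tokens)
  maxlen <- min(lex$max_term_len, n)
  if (n == 0L || maxlen == 0L) {
    return(tibble(message_id = character(0), term = character(0),
                  start = integer(0), end = integer(0), types = list()))
  }
  # precompute, per span length, which positions start a lexicon entry
  span <- vector("list", maxlen)
  span[[1]] <- tokens
  if (maxlen > 1) {
    for (len in 2:maxlen) {
      k <- n - len + 1L
      span[[len]] <- do.call(paste, lapply(seq_len(len), function(j) {
        tokens[j:(j + k - 1L)]
      }))
    }
  }
  hit <- lapply(span, function(s) !is.na(match(s, lex$entries$term)))
  out_start <- integer(0); out_len <- integer(0)
  i <- 1L
  while (i <= n) {
    adv <- 1L
    for (len in seq.int(min(maxlen, n - i + 1L), 1L)) {
      if (hit[[len]][i]) {
        out_start <- c(out_start, i)
        out_len <- c(out_len, len)
        adv <- len
        break
      }
    }
    i <- i + adv
  }
  terms <- vapply(seq_along(out_start), function(j) {
    span[[out_len[j]]][out_start[j]]
  }, character(1))
  tibble(message_id = rep(message_id, length(terms)),
         term = terms, start = out_start - 1L,
         end = out_start - 1L + out_len,
         types = lapply(terms, function(t) {
           get0(t, envir = lex$index, inherits = FALSE)
         }))
}

#' Match lexicon terms across a tokenized corpus
#'
#' @param tokenized list of tokenized messages (from [tokenize_corpus()]).
#' @param lex a [lexicon].
#' @return tibble of matches (as [match_terms()]) over all messages, in
#'   message then position order.
#' @export
match_corpus <- function(tokenized, lex) {
  res <- lapply(tokenized, function(tm) {
    match_terms(tm$content_tokens, lex, message_id = tm$message_id)
  })
  do.call(rbind, res)
}
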