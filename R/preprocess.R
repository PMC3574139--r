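#' Preprocessing configuration
#'
#' @param stoplist character vector of lowercase stop words; defaults to the
#'   packaged English list (see [default_stoplist()]).
#' @param use_stemming apply the Porter stemmer to content tokens.
#' @param min_token_len drop content tokens shorter than this many characters.
#' @param noise_min_content_tokens minimum number of content tokens a message
#'   must keep to survive noise filtering (in addition to carrying at least
#'   one medical-lexicon term).
#' @return a list of class `preprocess_config`.
#' @export
preprocess_config <- function(stoplist = default_stoplist(),
                              use_stemming = TRUE,
                              min_token_len = 2L,
                              noise_min_content_tokens = 1L) {
  stoplist <- unique(tolower(as.character(stoplist)))
  min_token_len <- as.integer(min_token_len)
  noise_min_content_tokens <- as.integer(noise_min_content_tokens)
  if (min_token_len < 1L) stop("min_token_len must be >= 1")
  if (noise_min_content_tokens < 0L) {
    stop("noise_min_content_tokens must be >= 0")
  }
  structure(list(stoplist = stoplist,
                 use_stemming = isTRUE(use_stemming),
                 min_token_len = min_token_len,
                 noise_min_content_tokens = noise_min_content_tokens),
            class = "preprocess_config")
}

#' Packaged default English stop-word list
#'
#' Read from `inst/extdata/stopwords.txt` (one word per line, `#` comments).
#' Override by passing your own vector or file to [preprocess_config()] /
#' [read_stoplist()].
#'
#' @return character vector of lowercase stop words.
#' @export
default_stoplist <- function() {
  read_stoplist(system.file("extdata", "stopwords.txt", package = "medtopic",
                            mustWork = TRUE))
}

#' Read a stop-word list file
#'
#' One word per line, UTF-8; blank lines and `#` comments ignored.
#'
#' @param path file path.
#' @return character vector of lowercase words.
#' @export
read_stoplist <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- tolower(trimws(lines))
  unique(lines[nzchar(lines)])
}

# lowercase word tokens: alphanumeric runs, keeping internal hyphens and
# apostrophes ("x-ray", "paget's") as single tokens
tokenize_text <- function(text) {
  if (is.na(text) || !nzchar(text)) return(character(0))
  text <- stringi::stri_trans_tolower(text)
  toks <- stringi::stri_extract_all_regex(
    text, "[\\p{L}\\p{N}]+(?:['\\-][\\p{L}\\p{N}]+)*")[[1]]
  if (length(toks) == 1 && is.na(toks)) character(0) else toks
}

#' Tokenize and normalize one message
#'
#' Lowercases and splits the text on non-alphanumeric characters (keeping
#' intra-word hyphens and apostrophes), then derives content tokens by
#' removing stop words and short tokens and applying the Porter stemmer.
#' Pure per-message: the result depends only on the message and the config.
#'
#' @param message one-row data frame with `id` and `text` (e.g. a row of
#'   `corpus$messages`), or a list with those fields.
#' @param config a [preprocess_config()].
#' @return a list of class `tokenized_message` with `message_id`,
#'   `raw_tokens`, `content_tokens`.
#' @export
tokenize_and_normalize <- function(message, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  raw <- tokenize_text(as.character(message$text)[1])
  content <- raw[!(raw %in% config$stoplist) &
                   nchar(raw) >= config$min_token_len]
  if (config$use_stemming && length(content) > 0) {
    content <- porter_stem(content)
  }
  structure(list(message_id = as.character(message$id)[1],
                 raw_tokens = raw,
                 content_tokens = content),
            class = "tokenized_message")
}

#' Tokenize every message of a corpus
#'
#' @param corp a [corpus].
#' @param config a [preprocess_config()].
#' @return list of `tokenized_message`, aligned with corpus order.
#' @export
tokenize_corpus <- function(corp, config = preprocess_config()) {
  stopifnot(inherits(corp, "corpus"))
  msgs <- corp$messages
  # batch path, result identical to per-message tokenize_and_normalize:
  # tokenize all texts at once and stem the corpus-wide token pool in one
  # call (the stemmer deduplicates internally)
  texts <- stringi::stri_trans_tolower(ifelse(is.na(msgs$text), "",
                                              msgs$text))
  raw_l <- stringi::stri_extract_all_regex(
    texts, "[\\p{L}\\p{N}]+(?:['\\-][\\p{L}\\p{N}]+)*", omit_no_match = TRUE)
  content_l <- lapply(raw_l, function(raw) {
    raw[!(raw %in% config$stoplist) & nchar(raw) >= config$min_token_len]
  })
  if (config$use_stemming) {
    flat <- unlist(content_l, use.names = FALSE)
    if (length(flat) > 0) {
      content_l <- utils::relist(porter_stem(flat), content_l)
    }
  }
  lapply(seq_len(nrow(msgs)), function(i) {
    structure(list(message_id = msgs$id[i],
                   raw_tokens = raw_l[[i]],
                   content_tokens = as.character(content_l[[i]])),
              class = "tokenized_message")
  })
}

#' Filter medically-empty noise messages
#'
#' Online health boards carry many messages of pure emotional support
#' ("Thank you for your answer", "I hope you get well soon") that contain no
#' medical information and would pollute topic clusters. A message is
#' retained iff it has at least `noise_min_content_tokens` content tokens AND
#' at least one medical-lexicon term match; everything else is removed.
#' Relative order is preserved, so filtering an already-filtered corpus is a
#' no-op.
#'
#' @param corp a [corpus].
#' @param tokenized list of tokenized messages aligned to `corp` by id
#'   (from [tokenize_corpus()]).
#' @param lex a [lexicon] used to detect medical terms.
#' @param config a [preprocess_config()].
#' @return the filtered [corpus].
#' @export
filter_noise_messages <- function(corp, tokenized, lex,
                                  config = preprocess_config()) {
  stopifnot(inherits(corp, "corpus"), inherits(lex, "lexicon"))
  ids <- vapply(tokenized, `[[`, character(1), "message_id")
  if (length(ids) != nrow(corp$messages) ||
      !identical(ids, corp$messages$id)) {
    stop("tokenized messages are not aligned with the corpus")
  }
  keep <- vapply(tokenized, function(tm) {
    length(tm$content_tokens) >= config$noise_min_content_tokens &&
      nrow(match_terms(tm$content_tokens, lex)) > 0
  }, logical(1))
  corpus(corp$messages[keep, , drop = FALSE],
         board_name = corp$board_name, disease_type = corp$disease_type)
}
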