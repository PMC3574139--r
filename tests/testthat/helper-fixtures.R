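# shared fixtures built in code

# a tiny corpus of hand-written board messages
tiny_corpus <- function() {
  corpus(tibble::tibble(
    id = c("m1", "m2", "m3"),
    author_id = c("a1", "a1", "a2"),
    board_id = "lung",
    timestamp = c("2004-03-15", "2010-07-01", "2012-03-02"),
    text = c("I am coughing up blood",
             "chest pain after chemo, \"scary\" stuff",
             "Thank you for your answer"),
    gold_label = c("Symptom", "Symptom", NA),
    thread_id = c("t1", "t1", "t2")
  ), board_name = "lung cancer", disease_type = "lung cancer")
}

# unstemmed lexicon over literal tokens, for hand-traceable matching
literal_lexicon <- function(terms, types) {
  lexicon(terms, types, stem = FALSE)
}

# tokenized_message built directly from tokens
tok_msg <- function(id, tokens) {
  structure(list(message_id = id, raw_tokens = tokens,
                 content_tokens = tokens),
            class = "tokenized_message")
}

write_tmp_lines <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path, useBytes = TRUE)
  path
}

# brute-force pair counting over all unordered pairs (quadratic oracle)
brute_pair_counts <- function(pred, true) {
  n <- length(pred)
  ss <- sd <- ds <- dd <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sp <- pred[i] == pred[j]
      st <- true[i] == true[j]
      if (sp && st) ss <- ss + 1L
      else if (sp && !st) sd <- sd + 1L
      else if (!sp && st) ds <- ds + 1L
      else dd <- dd + 1L
    }
  }
  list(SS = ss, SD = sd, DS = ds, DD = dd)
}

# brute-force greedy longest-match scan written independently of the
# package's hash-index implementation
brute_greedy_match <- function(tokens, entries) {
  # entries: named list term -> types; terms are space-joined token strings
  lens <- lengths(strsplit(names(entries), " "))
  out <- list()
  i <- 1L
  while (i <= length(tokens)) {
    found <- 0L
    for (len in sort(unique(lens), decreasing = TRUE)) {
      if (i + len - 1L > length(tokens)) next
      cand <- paste(tokens[i:(i + len - 1L)], collapse = " ")
      if (cand %in% names(entries)) { found <- len; break }
    }
    if (found > 0L) {
      cand <- paste(tokens[i:(i + found - 1L)], collapse = " ")
      out[[length(out) + 1L]] <- list(term = cand, start = i - 1L,
                                      end = i - 1L + found)
      i <- i + found
    } else {
      i <- i + 1L
    }
  }
  out
}
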