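test_that("generation is byte-identical under a fixed seed", {
  cfg <- synthetic_config(n_topics = 3, n_messages = 60, seed = 99)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a$corpus$messages, b$corpus$messages)
  expect_identical(a$truth, b$truth)
  expect_identical(a$lexicon$entries, b$lexicon$entries)

  c2 <- generate_corpus(synthetic_config(n_topics = 3, n_messages = 60,
                                         seed = 100))
  expect_false(identical(a$corpus$messages$text, c2$corpus$messages$text))
})

test_that("invalid configurations are rejected with the field named", {
  expect_error(synthetic_config(n_topics = 0), "n_topics")
  expect_error(synthetic_config(noise_rate = 1), "noise_rate")
  expect_error(synthetic_config(separation = 0.2, n_topics = 5),
               "separation")
  expect_error(synthetic_config(topic_term_rate = 0), "topic_term_rate")
  expect_error(synthetic_config(n_topics = 2,
                                type_profile = list("sosy")),
               "type_profile")
})

test_that("noise_rate 0 labels every message; noise carries no lexicon term", {
  sc0 <- generate_corpus(synthetic_config(n_topics = 3, n_messages = 80,
                                          noise_rate = 0, seed = 5))
  expect_false(anyNA(sc0$corpus$messages$gold_label))

  sc <- generate_corpus(synthetic_config(n_topics = 3, n_messages = 200,
                                         noise_rate = 0.3, seed = 6))
  expect_gt(sum(is.na(sc$truth)), 0)
  tok <- tokenize_corpus(sc$corpus, preprocess_config())
  for (i in which(is.na(sc$truth))) {
    expect_equal(nrow(match_terms(tok[[i]]$content_tokens, sc$lexicon)), 0L)
  }
  # and every labeled message carries at least one topic term
  for (i in which(!is.na(sc$truth))) {
    expect_gt(nrow(match_terms(tok[[i]]$content_tokens, sc$lexicon)), 0L)
  }
})

test_that("topic term sets are disjoint after stemming", {
  sc <- generate_corpus(synthetic_config(n_topics = 5, n_messages = 10,
                                         seed = 8))
  stem_set <- lapply(sc$topic_terms, function(terms) {
    vapply(strsplit(terms, " "), function(tk) {
      paste(porter_stem(tk), collapse = " ")
    }, character(1))
  })
  all_stems <- unlist(stem_set)
  expect_false(any(duplicated(all_stems)))
  expect_equal(nrow(sc$lexicon$entries), length(all_stems))
})

test_that("empirical topic shares and own-topic fraction match the config", {
  sep <- 0.9
  sc <- generate_corpus(synthetic_config(n_topics = 3, n_messages = 600,
                                         noise_rate = 0, separation = sep,
                                         seed = 7))
  counts <- table(sc$truth)
  n <- length(sc$truth)
  p <- 1 / 3
  bound <- 3 * sqrt(n * p * (1 - p))
  expect_true(all(abs(counts - n * p) <= bound))

  # own-topic fraction of matched terms within +/- 0.05 of separation
  term_topic <- rep(seq_along(sc$topic_terms), lengths(sc$topic_terms))
  names(term_topic) <- vapply(strsplit(unlist(sc$topic_terms), " "),
                              function(tk) paste(porter_stem(tk),
                                                 collapse = " "),
                              character(1))
  tok <- tokenize_corpus(sc$corpus, preprocess_config())
  m <- match_corpus(tok, sc$lexicon)
  msg_topic <- setNames(sc$truth, sc$corpus$messages$id)
  own <- term_topic[m$term] == msg_topic[m$message_id]
  expect_equal(mean(own), sep, tolerance = 0.05)
})

test_that("generated lexicons write as loadable TSV", {
  sc <- generate_corpus(synthetic_config(n_topics = 2, n_messages = 10,
                                         seed = 9))
  path <- tempfile(fileext = ".tsv")
  write_lexicon(sc$lexicon, path)
  back <- load_lexicon(path, stem = FALSE)  # already stemmed on generation
  expect_equal(nrow(back$entries), nrow(sc$lexicon$entries))
  expect_setequal(back$entries$term, sc$lexicon$entries$term)
})
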