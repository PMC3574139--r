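NOISE_PHRASES <- c(
  "Thank you for your answer",
  "I hope you get well soon",
  "Thinking of you and your family",
  "So sorry to hear that",
  "Good luck with everything",
  "Stay strong you are in my thoughts",
  "Sending prayers your way",
  "Take care and best wishes",
  "That is wonderful news congratulations",
  "Bless you all"
)

DEFAULT_TYPE_PROFILE <- list(c("sosy"), c("dsyn", "patf"), c("diap", "lbpr"),
                             c("topp"), c("phsu"))

#' Synthetic-corpus configuration
#'
#' Parameters of the generative model behind [generate_corpus()]: K latent
#' topics, each owning a disjoint set of typed medical terms; messages mix
#' Poisson numbers of topic terms and background words; a fraction of
#' messages are medically-empty emotional noise.
#'
#' @param n_topics number of latent topics K (default 5, one per topic
#'   category: Symptom, Complication, Examination, Procedure, Drug).
#' @param n_messages corpus size (default 2000).
#' @param background_vocab_size background vocabulary size (default 600).
#' @param terms_per_topic medical terms owned by each topic (default 10).
#' @param topic_term_rate expected topic-term tokens per message (Poisson,
#'   at least one term forced; default 20 — forum posts mention their key
#'   terms repeatedly).
#' @param background_rate expected background tokens per message (default
#'   40, giving ~60 content tokens, i.e. a 100-120-word post).
#' @param noise_rate fraction of medically-empty noise messages, in [0, 1)
#'   (default 0.1).
#' @param type_profile list of semantic-type vectors, one per topic; the
#'   default cycles the 5-category scheme sosy; dsyn/patf; diap/lbpr; topp;
#'   phsu.
#' @param separation probability that a topic-term token is drawn from the
#'   message's own topic (vs a random other topic); in (1/K, 1] (default
#'   0.9).
#' @param seed integer seed; the generated corpus is byte-identical for a
#'   given config.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_topics = 5L, n_messages = 2000L,
                             background_vocab_size = 600L,
                             terms_per_topic = 10L, topic_term_rate = 20,
                             background_rate = 40, noise_rate = 0.1,
                             type_profile = NULL, separation = 0.9,
                             seed = 42L) {
  cfg <- list(n_topics = as.integer(n_topics),
              n_messages = as.integer(n_messages),
              background_vocab_size = as.integer(background_vocab_size),
              terms_per_topic = as.integer(terms_per_topic),
              topic_term_rate = topic_term_rate,
              background_rate = background_rate,
              noise_rate = noise_rate,
              type_profile = type_profile,
              separation = separation,
              seed = as.integer(seed))
  if (cfg$n_topics < 1) stop("invalid config field: n_topics must be >= 1")
  if (cfg$n_messages < 1) stop("invalid config field: n_messages must be >= 1")
  if (cfg$background_vocab_size < 1) {
    stop("invalid config field: background_vocab_size must be >= 1")
  }
  if (cfg$terms_per_topic < 1) {
    stop("invalid config field: terms_per_topic must be >= 1")
  }
  if (cfg$topic_term_rate <= 0) {
    stop("invalid config field: topic_term_rate must be > 0")
  }
  if (cfg$background_rate <= 0) {
    stop("invalid config field: background_rate must be > 0")
  }
  if (cfg$noise_rate < 0 || cfg$noise_rate >= 1) {
    stop("invalid config field: noise_rate must be in [0, 1)")
  }
  if (cfg$n_topics > 1 &&
      (cfg$separation <= 1 / cfg$n_topics || cfg$separation > 1)) {
    stop("invalid config field: separation must be in (1/K, 1]")
  }
  if (is.null(cfg$type_profile)) {
    cfg$type_profile <- lapply(seq_len(cfg$n_topics), function(k) {
      DEFAULT_TYPE_PROFILE[[(k - 1L) %% length(DEFAULT_TYPE_PROFILE) + 1L]]
    })
  }
  if (length(cfg$type_profile) != cfg$n_topics) {
    stop("invalid config field: type_profile must have one entry per topic")
  }
  known <- semantic_types()$abbrev
  bad <- setdiff(unlist(cfg$type_profile), known)
  if (length(bad) > 0) {
    stop("invalid config field: type_profile has unknown type ", bad[1])
  }
  structure(cfg, class = "synthetic_config")
}

# pronounceable pseudo-words that are fixed points of the Porter stemmer
# (so lexicon and corpus normalize to themselves), unique and avoiding
# `reserved` stems; deterministic given the RNG state
make_words <- function(n, reserved = character(0)) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vows <- c("a", "e", "i", "o", "u")
  seen <- new.env(parent = emptyenv())
  for (r in reserved) assign(r, TRUE, envir = seen)
  out <- character(n)
  got <- 0L
  while (got < n) {
    nsyl <- sample(2:3, 1L)
    w <- paste0(paste0(sample(cons, nsyl, replace = TRUE),
                       sample(vows, nsyl, replace = TRUE)), collapse = "")
    if (porter_stem(w) == w &&
        is.null(get0(w, envir = seen, inherits = FALSE))) {
      assign(w, TRUE, envir = seen)
      got <- got + 1L
      out[got] <- w
    }
  }
  out
}

#' Generate a labeled synthetic message corpus
#'
#' Emulates the structure of disease discussion boards: each non-noise
#' message draws a topic uniformly, emits `max(1, Poisson(topic_term_rate))`
#' medical-term tokens — from its own topic's term set with probability
#' `separation`, otherwise from a random other topic's — plus
#' `Poisson(background_rate)` background words; noise messages combine an
#' emotional phrase ("Thank you for your answer", ...) with background words
#' and contain no lexicon term. Topic term sets are disjoint (also after
#' stemming), so ground-truth recovery is well-posed at high separation. A
#' matching lexicon typing each topic's terms with that topic's semantic
#' types is generated alongside.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_corpus` with `corpus` (a [corpus];
#'   `gold_label` = `topic_<k>` for non-noise messages, `NA` for noise),
#'   `lexicon` (a [lexicon]), `truth` (integer topic index per message, `NA`
#'   for noise), `topic_terms` (list of term-string vectors per topic).
#' @export
generate_corpus <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  K <- config$n_topics
  noise_words <- unique(tolower(unlist(strsplit(NOISE_PHRASES, " "))))
  reserved <- unique(porter_stem(noise_words))
  # background vocabulary, then disjoint per-topic term words
  bg_vocab <- make_words(config$background_vocab_size, reserved)
  reserved <- c(reserved, porter_stem(bg_vocab))
  topic_terms <- vector("list", K)
  lex_terms <- character(0)
  lex_types <- list()
  for (k in seq_len(K)) {
    # ~1/3 of each topic's terms are two-token phrases
    n_multi <- config$terms_per_topic %/% 3L
    n_single <- config$terms_per_topic - n_multi
    words <- make_words(n_single + 2L * n_multi, reserved)
    reserved <- c(reserved, porter_stem(words))
    singles <- words[seq_len(n_single)]
    multis <- if (n_multi > 0) {
      rest <- words[-seq_len(n_single)]
      vapply(seq_len(n_multi), function(j) {
        paste(rest[c(2L * j - 1L, 2L * j)], collapse = " ")
      }, character(1))
    } else {
      character(0)
    }
    terms <- c(singles, multis)
    topic_terms[[k]] <- terms
    types_k <- config$type_profile[[k]]
    lex_terms <- c(lex_terms, terms)
    lex_types <- c(lex_types, lapply(seq_along(terms), function(j) {
      types_k[(j - 1L) %% length(types_k) + 1L]
    }))
  }
  lex <- lexicon(lex_terms, lex_types, stem = TRUE)

  n <- config$n_messages
  is_noise <- runif(n) < config$noise_rate
  truth <- ifelse(is_noise, NA_integer_, sample.int(K, n, replace = TRUE))
  n_members <- max(1L, ceiling(n / 3))
  authors <- paste0("member_", sample.int(n_members, n, replace = TRUE))
  dates <- as.Date("2004-03-01") +
    sample.int(as.integer(as.Date("2012-03-31") - as.Date("2004-03-01")),
               n, replace = TRUE)
  texts <- character(n)
  for (i in seq_len(n)) {
    n_bg <- rpois(1L, config$background_rate)
    bg <- if (n_bg > 0) sample(bg_vocab, n_bg, replace = TRUE) else character(0)
    if (is_noise[i]) {
      units <- c(sample(NOISE_PHRASES, 1L), bg)
    } else {
      z <- truth[i]
      n_t <- max(1L, rpois(1L, config$topic_term_rate))
      own <- runif(n_t) < config$separation
      src <- integer(n_t)
      src[own] <- z
      if (any(!own) && K > 1) {
        src[!own] <- sample(setdiff(seq_len(K), z), sum(!own), replace = TRUE)
      } else {
        src[!own] <- z
      }
      terms <- vapply(src, function(k) {
        topic_terms[[k]][sample.int(length(topic_terms[[k]]), 1L)]
      }, character(1))
      units <- c(terms, bg)
    }
    texts[i] <- paste(sample(units), collapse = " ")
  }
  corp <- corpus(
    tibble(id = sprintf("msg_%06d", seq_len(n)),
           author_id = authors,
           board_id = "synthetic_board",
           timestamp = format(dates, "%Y-%m-%d"),
           text = texts,
           gold_label = ifelse(is.na(truth), NA_character_,
                               paste0("topic_", truth)),
           thread_id = NA_character_),
    board_name = "synthetic_board", disease_type = "synthetic")
  structure(list(corpus = corp, lexicon = lex, truth = truth,
                 topic_terms = topic_terms, config = config),
            class = "synthetic_corpus")
}

#' Write a generated lexicon as TSV
#'
#' @param lex a [lexicon].
#' @param path output path (`term<TAB>type1|type2`).
#' @export
write_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "lexicon"))
  lines <- vapply(seq_len(nrow(lex$entries)), function(i) {
    paste0(lex$entries$term[i], "\t",
           paste(lex$entries$types[[i]], collapse = "|"))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(NULL)
}
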