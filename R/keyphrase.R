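TOPIC_LABEL_MAP <- c(sosy = "Symptom", dsyn = "Complication",
                     patf = "Complication", diap = "Examination",
                     lbpr = "Examination", topp = "Procedure",
                     phsu = "Drug")

#' Per-cluster candidate-term frequencies
#'
#' Candidate key phrases are every content n-gram (n = 1, 2, 3) plus every
#' matched medical-lexicon term. For each candidate the total token
#' occurrence count f(w, C_i) in each cluster is tallied. (A config switch
#' for message-count — document-frequency — tallying is provided via
#' `count = "document"`.)
#'
#' @param tokenized list of tokenized messages.
#' @param matches match tibble from [match_corpus()].
#' @param hard_labels integer cluster label per message, aligned with
#'   `tokenized`; clusters are numbered 1..N.
#' @param count `"token"` (occurrences, default) or `"document"` (messages
#'   containing the term).
#' @return list with `terms` (character), `freq` (term x cluster count
#'   matrix) and `n_clusters`.
#' @export
term_cluster_frequencies <- function(tokenized, matches, hard_labels,
                                     count = c("token", "document")) {
  count <- match.arg(count)
  if (length(hard_labels) != length(tokenized)) {
    stop("hard_labels must align with the tokenized messages")
  }
  ids <- vapply(tokenized, `[[`, character(1), "message_id")
  if (nrow(matches) > 0 && !all(matches$message_id %in% ids)) {
    stop("matches reference message id(s) absent from the tokenized input")
  }
  N <- max(1L, max(as.integer(hard_labels)))
  labels <- as.integer(hard_labels)
  gram_lists <- lapply(tokenized, function(tm) {
    toks <- tm$content_tokens
    c(ngrams_of(toks, 1L), ngrams_of(toks, 2L), ngrams_of(toks, 3L))
  })
  occ_term <- unlist(gram_lists, use.names = FALSE)
  occ_cl <- rep.int(labels, lengths(gram_lists))
  if (nrow(matches) > 0) {
    occ_term <- c(occ_term, matches$term)
    occ_cl <- c(occ_cl, labels[match(matches$message_id, ids)])
  }
  if (count == "document") {
    occ_msg <- rep.int(seq_along(tokenized), lengths(gram_lists))
    if (nrow(matches) > 0) {
      occ_msg <- c(occ_msg, match(matches$message_id, ids))
    }
    dedup <- !duplicated(paste0(occ_msg, "\r", occ_term))
    occ_term <- occ_term[dedup]
    occ_cl <- occ_cl[dedup]
  }
  terms <- sort(unique(occ_term))
  ti <- match(occ_term, terms)
  code <- (occ_cl - 1) * length(terms) + ti
  freq <- matrix(tabulate(code, nbins = as.double(length(terms)) * N),
                 nrow = length(terms), dimnames = list(terms, NULL))
  list(terms = terms, freq = freq, n_clusters = N)
}

#' Score key phrases per cluster
#'
#' TF-IDF-like score: score(w, C_i) = f(w, C_i) * log(N / n_w), natural log,
#' where f is the term's frequency in cluster C_i, N the number of clusters
#' and n_w the number of clusters whose frequency of w is greater than or
#' equal to f(w, C_i) (the cluster itself always qualifies, so n_w >= 1). A
#' term spread evenly over all clusters scores 0; a term exclusive to one
#' cluster scores f * log(N) there.
#'
#' @param freqs a [term_cluster_frequencies()] result.
#' @param top_m how many phrases to keep per cluster (default 10).
#' @return list of per-cluster tibbles (rank, term, f, n_w, score), sorted
#'   by descending score with lexicographic tie-break.
#' @export
score_keyphrases <- function(freqs, top_m = 10L) {
  top_m <- as.integer(top_m)
  if (top_m < 1L) stop("top_m must be >= 1")
  N <- freqs$n_clusters
  F <- freqs$freq
  out <- vector("list", N)
  for (i in seq_len(N)) {
    f_i <- F[, i]
    keep <- which(f_i > 0)
    if (length(keep) == 0) {
      out[[i]] <- tibble(rank = integer(0), term = character(0),
                         f = numeric(0), n_w = integer(0), score = numeric(0))
      next
    }
    n_w <- rowSums(F[keep, , drop = FALSE] >= f_i[keep])
    score <- f_i[keep] * log(N / n_w)
    ord <- order(-score, freqs$terms[keep])
    sel <- ord[seq_len(min(top_m, length(ord)))]
    out[[i]] <- tibble(rank = seq_along(sel),
                       term = freqs$terms[keep][sel],
                       f = as.numeric(unname(f_i[keep][sel])),
                       n_w = as.integer(unname(n_w[sel])),
                       score = unname(score[sel]))
  }
  out
}

#' Label clusters with topic categories from dominant semantic types
#'
#' For each cluster, semantic types are ranked by their summed counts over
#' member messages; the top type maps to a topic category: sosy -> Symptom;
#' dsyn or patf -> Complication; diap or lbpr -> Examination; topp ->
#' Procedure; phsu -> Drug; anything else (or no counts at all) -> Other.
#' Clusters sharing a label are reported as mergeable.
#'
#' @param hard_labels integer cluster label per message (1..N).
#' @param sem_type_counts numeric matrix, messages x semantic types (e.g.
#'   the `sem_type` block of a feature matrix, columns named by abbrev or
#'   `sem_type:abbrev`).
#' @param scores optional [score_keyphrases()] output; its top terms are
#'   attached to each label.
#' @return tibble with columns `cluster_id`, `label`, `dominant_types`
#'   (list-column, ranked), `top_phrases` (list-column), `mergeable_with`
#'   (list-column of other cluster ids sharing the label).
#' @export
label_clusters <- function(hard_labels, sem_type_counts, scores = NULL) {
  sem_type_counts <- as.matrix(sem_type_counts)
  cn <- sub("^sem_type:", "", colnames(sem_type_counts))
  colnames(sem_type_counts) <- cn
  N <- max(1L, max(as.integer(hard_labels)))
  labels <- character(N)
  dom <- vector("list", N)
  phrases <- vector("list", N)
  for (i in seq_len(N)) {
    rows <- which(hard_labels == i)
    tot <- if (length(rows) == 0) {
      setNames(numeric(length(cn)), cn)
    } else {
      colSums(sem_type_counts[rows, , drop = FALSE])
    }
    pos <- tot[tot > 0]
    if (length(pos) == 0) {
      labels[i] <- "Other"
      dom[[i]] <- character(0)
    } else {
      ranked <- names(sort(pos, decreasing = TRUE))
      dom[[i]] <- ranked
      top <- ranked[1]
      labels[i] <- if (top %in% names(TOPIC_LABEL_MAP)) {
        TOPIC_LABEL_MAP[[top]]
      } else {
        "Other"
      }
    }
    phrases[[i]] <- if (!is.null(scores) && length(scores) >= i) {
      scores[[i]]$term
    } else {
      character(0)
    }
  }
  mergeable <- lapply(seq_len(N), function(i) {
    setdiff(which(labels == labels[i] & labels != "Other"), i)
  })
  tibble(cluster_id = seq_len(N), label = labels, dominant_types = dom,
         top_phrases = phrases, mergeable_with = mergeable)
}

#' Write per-cluster key-phrase tables as TSV
#'
#' @param scores a [score_keyphrases()] result.
#' @param path output TSV path (columns: cluster, rank, term, f, n_w, score).
#' @export
write_keyphrases <- function(scores, path) {
  rows <- do.call(rbind, lapply(seq_along(scores), function(i) {
    s <- scores[[i]]
    if (nrow(s) == 0) return(NULL)
    cbind(cluster = i, as.data.frame(s))
  }))
  if (is.null(rows)) {
    rows <- data.frame(cluster = integer(0), rank = integer(0),
                       term = character(0), f = numeric(0),
                       n_w = integer(0), score = numeric(0))
  }
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
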