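#' Pipeline configuration
#'
#' Bundles the stage configurations of the full topic-detection run:
#' read, preprocess, term matching, featurization, PCA, EM clustering,
#' key-phrase scoring and (when gold labels are present) external
#' evaluation.
#'
#' @param corpus a [corpus] object or a path readable by [read_corpus()].
#' @param lexicon a [lexicon] object or a TSV path for [load_lexicon()].
#' @param stoplist character vector, a stoplist file path, or `NULL` for the
#'   packaged default list.
#' @param preprocess a [preprocess_config()].
#' @param min_df n-gram document-frequency threshold (default 3).
#' @param feature_blocks blocks to cluster on: `"F1"` (keyword n-grams),
#'   `"F2"` (medical terms + semantic types) or `c("F1", "F2")` (default).
#' @param coverage_target PCA explained-variance target (default 0.95).
#' @param max_components cap on retained principal components (default 30).
#' @param em an [em_config()]; its seed is overridden by `seed`.
#' @param k fixed number of clusters, or `NULL` (default) to select it by
#'   cross-validated held-out likelihood.
#' @param top_m key phrases reported per cluster (default 10).
#' @param seed master seed for the run.
#' @param output_dir optional directory receiving `report.json`,
#'   `keyphrases.tsv` and `model.json`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(corpus, lexicon, stoplist = NULL,
                            preprocess = preprocess_config(),
                            min_df = 3L,
                            feature_blocks = c("F1", "F2"),
                            coverage_target = 0.95,
                            max_components = 30L,
                            em = em_config(),
                            k = NULL,
                            top_m = 10L,
                            seed = 1L,
                            output_dir = NULL) {
  structure(list(corpus = corpus, lexicon = lexicon, stoplist = stoplist,
                 preprocess = preprocess, min_df = as.integer(min_df),
                 feature_blocks = feature_blocks,
                 coverage_target = coverage_target,
                 max_components = max_components, em = em, k = k,
                 top_m = as.integer(top_m), seed = as.integer(seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full topic-detection pipeline
#'
#' Fixed stage order: read -> tokenize/normalize -> noise filter -> term
#' matching -> feature matrix (five blocks) -> block selection -> PCA ->
#' EM clustering (K chosen by cross-validated likelihood unless fixed) ->
#' key-phrase scoring -> topic labeling -> merging of clusters that share a
#' semantic-type-derived topic label into topic groups -> external
#' evaluation on the topic groups (only when gold labels are present; the
#' unmerged indices are reported alongside). All randomness flows from
#' `config$seed`; a rerun with the same config reproduces every numeric
#' field.
#'
#' @param config a [pipeline_config()].
#' @param verbose log per-stage row/column counts via `message()` (default
#'   TRUE).
#' @return list of class `run_report`: corpus stats, retained message count,
#'   `k_mixture` (CV-chosen mixture components) and `cv_curve`, `k_topics`
#'   and `topic_groups` (after the merge), per-cluster labels with key
#'   phrases, per-message topic group, evaluation (`NULL` without gold
#'   labels), seed and package version.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_ <- function(...) if (verbose) message(sprintf(...))

  corp <- pipeline_stage("read", {
    if (inherits(config$corpus, "corpus")) config$corpus
    else read_corpus(config$corpus)
  })
  lex <- pipeline_stage("lexicon", {
    if (inherits(config$lexicon, "lexicon")) config$lexicon
    else load_lexicon(config$lexicon)
  })
  pp <- config$preprocess
  if (!is.null(config$stoplist)) {
    sl <- if (length(config$stoplist) == 1 && file.exists(config$stoplist)) {
      read_stoplist(config$stoplist)
    } else {
      config$stoplist
    }
    pp <- preprocess_config(stoplist = sl,
                            use_stemming = pp$use_stemming,
                            min_token_len = pp$min_token_len,
                            noise_min_content_tokens = pp$noise_min_content_tokens)
  }
  stats <- corpus_stats(corp)
  log_("read: %d message(s), %d member(s)", stats$n_messages, stats$n_members)

  tokenized <- pipeline_stage("preprocess", tokenize_corpus(corp, pp))
  # one matching pass serves both the noise filter and the feature matrix
  matches_all <- pipeline_stage("match", match_corpus(tokenized, lex))
  keep <- vapply(tokenized, function(tm) {
    length(tm$content_tokens) >= pp$noise_min_content_tokens
  }, logical(1)) & corp$messages$id %in% matches_all$message_id
  filtered <- pipeline_stage("noise_filter",
                             corpus(corp$messages[keep, , drop = FALSE],
                                    board_name = corp$board_name,
                                    disease_type = corp$disease_type))
  tokenized <- tokenized[keep]
  log_("noise filter: %d of %d message(s) retained",
       nrow(filtered$messages), nrow(corp$messages))
  if (nrow(filtered$messages) < 2) {
    stop("[noise_filter] fewer than 2 messages survive filtering")
  }

  matches <- matches_all[matches_all$message_id %in% filtered$messages$id, ]
  log_("match: %d term occurrence(s), %d distinct term(s)",
       nrow(matches), length(unique(matches$term)))

  voc <- pipeline_stage("features",
                        build_vocabulary(tokenized, matches,
                                         min_df = config$min_df))
  fm <- pipeline_stage("features", vectorize(tokenized, matches, voc))
  log_("features: %d x %d count matrix", nrow(fm$values), ncol(fm$values))

  fm_sel <- pipeline_stage("features",
                           select_blocks(fm, config$feature_blocks))
  log_("feature blocks %s: %d column(s)",
       paste(config$feature_blocks, collapse = "+"), ncol(fm_sel$values))

  pca <- pipeline_stage("pca", fit_pca(fm_sel, config$coverage_target,
                                       config$max_components))
  X <- pipeline_stage("pca", pca_transform(pca, fm_sel))
  log_("pca: %d component(s) covering %.1f%% of variance", ncol(X),
       100 * sum(pca$explained_variance_ratio))

  em_cfg <- config$em
  em_cfg$seed <- config$seed
  if (is.null(config$k)) {
    sel <- pipeline_stage("select_k", select_k_cv(X, em_cfg))
    chosen_k <- sel$best_k
    cv_curve <- sel$cv_curve
  } else {
    chosen_k <- as.integer(config$k)
    cv_curve <- NULL
  }
  log_("clustering: K = %d", chosen_k)
  fit <- pipeline_stage("em", fit_em(X, chosen_k, em_cfg))
  hard <- fit$assignment$hard_labels

  freqs <- pipeline_stage("keyphrase",
                          term_cluster_frequencies(tokenized, matches, hard))
  scores <- pipeline_stage("keyphrase",
                           score_keyphrases(freqs, top_m = config$top_m))
  sem_block <- fm$values[, fm$vocabulary$block == "sem_type", drop = FALSE]
  labels <- pipeline_stage("label", label_clusters(hard, sem_block, scores))

  # topic identification: incorporate clusters with similar semantic types
  # into one topic group per label (Other clusters stay separate)
  group_of <- ifelse(labels$label == "Other",
                     paste0("Other_", labels$cluster_id), labels$label)
  topic_groups <- unique(group_of)
  merged <- group_of[hard]
  k_topics <- length(topic_groups)
  log_("topic groups: %d (%s)", k_topics, paste(topic_groups, collapse = ", "))

  gold <- filtered$messages$gold_label
  evaluation <- NULL
  if (any(!is.na(gold))) {
    ok <- !is.na(gold)
    ev <- pipeline_stage("evaluate",
                         evaluate_clustering(merged[ok], gold[ok]))
    ev_raw <- pipeline_stage("evaluate",
                             evaluate_clustering(hard[ok], gold[ok]))
    # map each topic group to its gold-majority category for a kappa-style
    # agreement figure on a shared label alphabet
    mapped <- vapply(topic_groups, function(g) {
      gg <- gold[ok][merged[ok] == g]
      if (length(gg) == 0) "none"
      else names(sort(table(gg), decreasing = TRUE))[1]
    }, character(1))
    kp <- pipeline_stage("evaluate",
                         cohens_kappa(mapped[match(merged[ok], topic_groups)],
                                      gold[ok]))
    evaluation <- list(counts = ev$counts, indices = ev$indices,
                       indices_unmerged = ev_raw$indices, kappa = kp,
                       n_evaluated = sum(ok))
    log_("evaluate (topic groups): Rand %.3f, Jaccard %.3f, FM %.3f (n = %d)",
         ev$indices$rand, ev$indices$jaccard, ev$indices$fm, sum(ok))
  }

  report <- structure(list(
    corpus_stats = stats,
    n_retained = nrow(filtered$messages),
    feature_blocks = config$feature_blocks,
    n_features = ncol(fm_sel$values),
    n_components = ncol(X),
    k_mixture = chosen_k,
    k_topics = k_topics,
    topic_groups = topic_groups,
    cv_curve = cv_curve,
    cluster_labels = labels,
    message_topic_group = merged,
    keyphrases = scores,
    evaluation = evaluation,
    config_echo = list(
      feature_blocks = config$feature_blocks, min_df = config$min_df,
      coverage_target = config$coverage_target,
      max_components = config$max_components,
      k_fixed = config$k, top_m = config$top_m,
      em = unclass(em_cfg),
      preprocess = list(use_stemming = pp$use_stemming,
                        min_token_len = pp$min_token_len,
                        noise_min_content_tokens = pp$noise_min_content_tokens,
                        n_stopwords = length(pp$stoplist))),
    seed = config$seed,
    version = as.character(utils::packageVersion("medtopic"))
  ), class = "run_report")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_run_report(report, file.path(config$output_dir, "report.json"))
    write_keyphrases(scores, file.path(config$output_dir, "keyphrases.tsv"))
    write_mixture_model(fit$model, file.path(config$output_dir, "model.json"))
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf(paste0("<run_report> %d mixture component(s) -> %d topic ",
                     "group(s), %d message(s), %s features\n"),
              x$k_mixture, x$k_topics, x$n_retained,
              paste(x$feature_blocks, collapse = "+")))
  for (i in seq_len(nrow(x$cluster_labels))) {
    cat(sprintf("  cluster %d [%s]: %s\n", i, x$cluster_labels$label[i],
                paste(head(x$cluster_labels$top_phrases[[i]], 5),
                      collapse = ", ")))
  }
  if (!is.null(x$evaluation)) {
    cat(sprintf("  Rand %.3f  Jaccard %.3f  FM %.3f  kappa %.3f\n",
                x$evaluation$indices$rand, x$evaluation$indices$jaccard,
                x$evaluation$indices$fm, x$evaluation$kappa$kappa))
  }
  invisible(x)
}

#' Serialize a run report as JSON
#'
#' @param report a `run_report`.
#' @param path JSON output path.
#' @export
write_run_report <- function(report, path) {
  obj <- list(
    corpus_stats = unclass(report$corpus_stats),
    n_retained = report$n_retained,
    feature_blocks = report$feature_blocks,
    n_features = report$n_features,
    n_components = report$n_components,
    k_mixture = report$k_mixture,
    k_topics = report$k_topics,
    topic_groups = report$topic_groups,
    cv_curve = as.list(report$cv_curve),
    cluster_labels = lapply(seq_len(nrow(report$cluster_labels)), function(i) {
      list(cluster_id = report$cluster_labels$cluster_id[i],
           label = report$cluster_labels$label[i],
           dominant_types = report$cluster_labels$dominant_types[[i]],
           top_phrases = report$cluster_labels$top_phrases[[i]])
    }),
    evaluation = if (is.null(report$evaluation)) NULL else list(
      SS = report$evaluation$counts$SS, SD = report$evaluation$counts$SD,
      DS = report$evaluation$counts$DS, DD = report$evaluation$counts$DD,
      rand = report$evaluation$indices$rand,
      jaccard = report$evaluation$indices$jaccard,
      fm = report$evaluation$indices$fm,
      rand_unmerged = report$evaluation$indices_unmerged$rand,
      jaccard_unmerged = report$evaluation$indices_unmerged$jaccard,
      fm_unmerged = report$evaluation$indices_unmerged$fm,
      kappa = report$evaluation$kappa$kappa,
      n_evaluated = report$evaluation$n_evaluated),
    config_echo = report$config_echo,
    seed = report$seed,
    version = report$version
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(NULL)
}
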