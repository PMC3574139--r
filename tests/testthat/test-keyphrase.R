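no_matches <- function() {
  tibble::tibble(message_id = character(0), term = character(0),
                 start = integer(0), end = integer(0), types = list())
}

test_that("per-cluster term frequencies tally token occurrences", {
  tok <- list(tok_msg("m1", c("pain", "pain")), tok_msg("m2", c("sleep")),
              tok_msg("m3", c("sleep", "pain")))
  f <- term_cluster_frequencies(tok, no_matches(), c(1L, 2L, 3L))
  expect_equal(f$n_clusters, 3L)
  expect_equal(as.numeric(f$freq["pain", ]), c(2, 0, 1))
  # a term present only in cluster 1
  expect_equal(as.numeric(f$freq["pain pain", ]), c(1, 0, 0))
})

test_that("cluster relabeling permutes frequency columns identically", {
  set.seed(51)
  tok <- lapply(1:8, function(i) {
    tok_msg(paste0("m", i), sample(letters[1:5], 6, replace = TRUE))
  })
  lab <- sample(1:3, 8, replace = TRUE)
  perm <- c(3L, 1L, 2L)
  f1 <- term_cluster_frequencies(tok, no_matches(), lab)
  f2 <- term_cluster_frequencies(tok, no_matches(), perm[lab])
  expect_identical(f1$terms, f2$terms)
  for (cl in 1:3) {
    expect_equal(f1$freq[, cl], f2$freq[, perm[cl]])
  }
})

test_that("frequencies equal a brute-force per-message recount", {
  set.seed(52)
  tok <- lapply(1:6, function(i) {
    tok_msg(paste0("m", i), sample(c("a", "b", "c"), 5, replace = TRUE))
  })
  lab <- c(1L, 1L, 1L, 2L, 2L, 2L)
  f <- term_cluster_frequencies(tok, no_matches(), lab)
  for (t in f$terms) {
    for (cl in 1:2) {
      want <- 0
      for (i in which(lab == cl)) {
        toks <- tok[[i]]$content_tokens
        grams <- c(toks,
                   if (length(toks) > 1)
                     paste(toks[-length(toks)], toks[-1]),
                   if (length(toks) > 2)
                     paste(toks[1:(length(toks) - 2)],
                           toks[2:(length(toks) - 1)],
                           toks[3:length(toks)]))
        want <- want + sum(grams == t)
      }
      expect_equal(unname(f$freq[t, cl]), want)
    }
  }
})

test_that("key-phrase scores follow f * log(N / n_w)", {
  # term exclusive to cluster 1, term uniform across clusters, and the
  # (4, 2, 2) fixture
  f <- list(terms = c("excl", "unif", "mix"),
            freq = rbind(c(5, 0, 0), c(3, 3, 3), c(4, 2, 2)),
            n_clusters = 3L)
  rownames(f$freq) <- f$terms
  s <- score_keyphrases(f, top_m = 10)
  s1 <- s[[1]]
  expect_equal(s1$score[s1$term == "excl"], 5 * log(3), tolerance = 1e-12)
  expect_equal(s1$score[s1$term == "unif"], 0)
  expect_equal(s1$score[s1$term == "mix"], 4 * log(3), tolerance = 1e-12)
  # clusters 2 and 3 see "mix" with n_w = 3 (ties count), so score 0
  for (cl in 2:3) {
    sc <- s[[cl]]
    expect_equal(sc$score[sc$term == "mix"], 0)
  }
  expect_error(score_keyphrases(f, top_m = 0), ">= 1")
})

test_that("scores are monotone in f and antitone in n_w", {
  N <- 4
  f_vals <- 1:6
  scores_f <- f_vals * log(N / 2)
  expect_true(all(diff(scores_f) > 0))
  nw_vals <- 1:4
  scores_nw <- 3 * log(N / nw_vals)
  expect_true(all(diff(scores_nw) < 0))
  expect_equal(scores_nw[4], 0)
})

test_that("ranking is by descending score with lexicographic tie-break", {
  f <- list(terms = c("zeta", "alpha", "mid"),
            freq = rbind(c(2, 0), c(2, 0), c(3, 0)),
            n_clusters = 2L)
  rownames(f$freq) <- f$terms
  s <- score_keyphrases(f, top_m = 3)[[1]]
  expect_identical(s$term, c("mid", "alpha", "zeta"))
  expect_equal(s$rank, 1:3)
  # top_m truncates
  s2 <- score_keyphrases(f, top_m = 1)[[1]]
  expect_identical(s2$term, "mid")
})

test_that("dominant semantic types map to the five topic categories", {
  sem <- matrix(0, nrow = 5, ncol = 3,
                dimnames = list(NULL, c("sosy", "dsyn", "phsu")))
  sem[1, "sosy"] <- 4          # cluster 1 dominated by sign-or-symptom
  sem[2, "dsyn"] <- 3          # cluster 2 by disease-or-syndrome
  sem[3, "phsu"] <- 5          # cluster 3 by pharmacologic substance
  sem[4, ] <- c(1, 0, 3)       # cluster 4 mixed, phsu dominates
  # cluster 5 has no counts at all
  labs <- label_clusters(1:5, sem)
  expect_identical(labs$label, c("Symptom", "Complication", "Drug", "Drug",
                                 "Other"))
  expect_identical(labs$dominant_types[[4]][1], "phsu")
  # clusters 3 and 4 share the Drug label and are mutually mergeable
  expect_equal(labs$mergeable_with[[3]], 4)
  expect_equal(labs$mergeable_with[[4]], 3)
  expect_length(labs$mergeable_with[[5]], 0)
})

test_that("each mapped type produces its documented category", {
  for (case in list(c("sosy", "Symptom"), c("dsyn", "Complication"),
                    c("patf", "Complication"), c("diap", "Examination"),
                    c("lbpr", "Examination"), c("topp", "Procedure"),
                    c("phsu", "Drug"), c("bpoc", "Other"))) {
    sem <- matrix(2, nrow = 1, ncol = 1, dimnames = list(NULL, case[1]))
    expect_identical(label_clusters(1L, sem)$label, case[2])
  }
})

test_that("keyphrase tables write as TSV", {
  f <- list(terms = c("a", "b"), freq = rbind(c(2, 0), c(1, 1)),
            n_clusters = 2L)
  rownames(f$freq) <- f$terms
  s <- score_keyphrases(f, top_m = 5)
  path <- tempfile(fileext = ".tsv")
  write_keyphrases(s, path)
  df <- read.delim(path)
  expect_identical(names(df), c("cluster", "rank", "term", "f", "n_w",
                                "score"))
  expect_true(all(df$cluster %in% 1:2))
})
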