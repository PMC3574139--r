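make_matches <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    tibble::tibble(message_id = r$id, term = r$term, start = r$start,
                   end = r$end, types = list(r$types))
  }))
}

no_matches <- function() {
  tibble::tibble(message_id = character(0), term = character(0),
                 start = integer(0), end = integer(0), types = list())
}

test_that("vocabulary applies the document-frequency threshold per block", {
  tok <- list(tok_msg("m1", c("pain", "chest")),
              tok_msg("m2", c("pain", "night")))
  voc <- build_vocabulary(tok, no_matches(), min_df = 2L)
  expect_identical(voc$unigrams, "pain")
  expect_identical(voc$bigrams, character(0))
  expect_length(voc$sem_types, 20L)
  expect_identical(voc$med_terms, character(0))
})

test_that("n-grams are enumerated contiguously", {
  tok <- list(tok_msg("m1", c("a", "b", "c")))
  voc <- build_vocabulary(tok, no_matches(), min_df = 1L)
  expect_identical(voc$unigrams, c("a", "b", "c"))
  expect_identical(voc$bigrams, c("a b", "b c"))
  expect_identical(voc$trigrams, "a b c")
  expect_error(build_vocabulary(list(), no_matches(), 1L), "zero messages")
})

test_that("semantic-type cells sum match type multiplicities", {
  tok <- list(tok_msg("m1", c("chest", "pain", "pain")),
              tok_msg("m2", character(0)))
  matches <- make_matches(
    list(id = "m1", term = "chest pain", start = 0L, end = 2L,
         types = "sosy"),
    list(id = "m1", term = "pain", start = 2L, end = 3L, types = "sosy"))
  voc <- build_vocabulary(tok, matches, min_df = 1L)
  fm <- vectorize(tok, matches, voc)
  expect_equal(fm$values["m1", "sem_type:sosy"], 2L)
  expect_equal(fm$values["m1", "med_term:chest pain"], 1L)
  expect_equal(fm$values["m1", "med_term:pain"], 1L)
  # unigram counts are raw occurrences
  expect_equal(fm$values["m1", "unigram:pain"], 2L)
  # empty message gives an all-zero row
  expect_true(all(fm$values["m2", ] == 0L))
})

test_that("a multi-type term increments every one of its type columns", {
  tok <- list(tok_msg("m1", c("infection")))
  matches <- make_matches(list(id = "m1", term = "infection", start = 0L,
                               end = 1L, types = c("dsyn", "patf")))
  voc <- build_vocabulary(tok, matches, min_df = 1L)
  fm <- vectorize(tok, matches, voc)
  expect_equal(fm$values["m1", "sem_type:dsyn"], 1L)
  expect_equal(fm$values["m1", "sem_type:patf"], 1L)
  expect_equal(sum(fm$values["m1", fm$vocabulary$block == "sem_type"]), 2L)
})

test_that("block selection slices columns and preserves rows", {
  tok <- list(tok_msg("m1", c("pain", "chest")),
              tok_msg("m2", c("pain", "x")))
  matches <- make_matches(list(id = "m2", term = "pain", start = 0L,
                               end = 1L, types = "sosy"))
  voc <- build_vocabulary(tok, matches, min_df = 1L)
  fm <- vectorize(tok, matches, voc)

  f1 <- select_blocks(fm, "F1")
  expect_false(any(f1$vocabulary$block %in% c("med_term", "sem_type")))
  expect_identical(f1$row_ids, fm$row_ids)

  all_blocks <- select_blocks(fm, c("F1", "F2"))
  expect_identical(all_blocks$values, fm$values)

  st <- select_blocks(fm, "sem_type")
  expect_equal(ncol(st$values), 20L)
  expect_error(select_blocks(fm, character(0)), "non-empty")
  expect_error(select_blocks(fm, "nope"), "unknown")
})

test_that("sem-type column sums conserve match type multiplicities per row", {
  set.seed(21)
  terms <- c("t1", "t2", "t3")
  type_sets <- list("sosy", c("dsyn", "patf"), c("diap", "lbpr", "topp"))
  tok <- lapply(1:6, function(i) {
    tok_msg(paste0("m", i), sample(c(terms, letters[1:4]), 8, replace = TRUE))
  })
  rows <- list()
  for (i in 1:6) {
    for (j in seq_along(terms)) {
      k <- sum(tok[[i]]$content_tokens == terms[j])
      if (k > 0) {
        for (r in seq_len(k)) {
          rows[[length(rows) + 1]] <- list(id = paste0("m", i),
                                           term = terms[j], start = 0L,
                                           end = 1L, types = type_sets[[j]])
        }
      }
    }
  }
  matches <- do.call(make_matches, rows)
  voc <- build_vocabulary(tok, matches, min_df = 1L)
  fm <- vectorize(tok, matches, voc)
  sem <- fm$values[, fm$vocabulary$block == "sem_type", drop = FALSE]
  for (i in 1:6) {
    id <- paste0("m", i)
    want <- sum(lengths(matches$types[matches$message_id == id]))
    expect_equal(sum(sem[id, ]), want)
  }
})

test_that("vectorize is permutation-equivariant in the messages", {
  tok <- list(tok_msg("m1", c("a", "b")), tok_msg("m2", c("b", "c")),
              tok_msg("m3", c("c", "a")))
  voc <- build_vocabulary(tok, no_matches(), min_df = 1L)
  fm <- vectorize(tok, no_matches(), voc)
  perm <- c(3, 1, 2)
  fm_p <- vectorize(tok[perm], no_matches(), voc)
  expect_identical(fm_p$values, fm$values[perm, ])
})

test_that("feature matrices export to sparse text plus vocabulary JSON", {
  tok <- list(tok_msg("m1", c("a", "b", "a")))
  voc <- build_vocabulary(tok, no_matches(), min_df = 1L)
  fm <- vectorize(tok, no_matches(), voc)
  mtx <- tempfile(fileext = ".mtx"); vj <- tempfile(fileext = ".json")
  export_feature_matrix(fm, mtx, vj)
  lines <- readLines(mtx)
  expect_match(lines[1], "MatrixMarket")
  dims <- as.integer(strsplit(lines[2], " ")[[1]])
  expect_equal(dims[1], 1L)
  expect_equal(dims[3], sum(fm$values != 0))
  vocab <- jsonlite::fromJSON(vj)
  expect_identical(vocab$row_ids, "m1")
})
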