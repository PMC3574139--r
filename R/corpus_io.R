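#' @importFrom tibble tibble as_tibble
#' @importFrom stats rpois runif sd var setNames
#' @importFrom utils head tail read.csv write.csv read.delim write.table packageVersion
NULL

CORPUS_FIELDS <- c("id", "author_id", "board_id", "timestamp", "text",
                   "gold_label", "thread_id")

#' Construct a message corpus
#'
#' A corpus is an ordered collection of forum messages with board-level
#' metadata. Each message carries an id, author, board, timestamp, free text,
#' and optionally a gold topic label and a thread id.
#'
#' @param messages data frame (or tibble) with at least columns `id`,
#'   `author_id`, `text`; optional columns `board_id`, `timestamp`,
#'   `gold_label`, `thread_id` are filled with `NA` when absent.
#' @param board_name,disease_type board-level metadata strings.
#' @return an object of class `corpus`: a list with elements `messages`
#'   (tibble, one row per message, in input order), `board_name`,
#'   `disease_type`.
#' @export
corpus <- function(messages, board_name = "", disease_type = "") {
  messages <- as_tibble(as.data.frame(messages, stringsAsFactors = FALSE))
  required <- c("id", "author_id", "text")
  missing <- setdiff(required, names(messages))
  if (length(missing) > 0) {
    stop("corpus messages lack required column(s): ",
         paste(missing, collapse = ", "))
  }
  for (f in CORPUS_FIELDS) {
    if (!f %in% names(messages)) messages[[f]] <- NA_character_
    messages[[f]] <- as.character(messages[[f]])
  }
  messages <- messages[, CORPUS_FIELDS]
  if (nrow(messages) > 0) {
    if (anyNA(messages$id) || any(!nzchar(messages$id))) {
      stop("corpus message ids must be non-empty")
    }
    dup <- duplicated(messages$id)
    if (any(dup)) {
      stop("duplicate message id(s): ",
           paste(unique(messages$id[dup]), collapse = ", "))
    }
  }
  structure(list(messages = messages,
                 board_name = as.character(board_name)[1],
                 disease_type = as.character(disease_type)[1]),
            class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("<corpus> %d message(s)", nrow(x$messages)))
  if (nzchar(x$board_name)) cat(sprintf(" | board: %s", x$board_name))
  if (nzchar(x$disease_type)) cat(sprintf(" | disease: %s", x$disease_type))
  cat("\n")
  print(head(x$messages, 5))
  invisible(x)
}

#' @export
length.corpus <- function(x) nrow(x$messages)

#' Read a message corpus from JSONL or CSV
#'
#' JSONL is the canonical format: one UTF-8 JSON object per line with keys
#' `id`, `author_id`, `board_id`, `timestamp`, `text`, `gold_label`,
#' `thread_id`. CSV uses the same columns (header row mandatory, RFC-4180
#' quoting). Record order is preserved; missing optional fields become `NA`.
#'
#' @param path file path.
#' @param format `"jsonl"` or `"csv"`; default guessed from the extension.
#' @param board_name,disease_type metadata attached to the returned corpus.
#' @return a [corpus].
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "csv"),
                        board_name = "", disease_type = "") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("corpus file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines_keep <- which(nzchar(trimws(lines)))
    records <- vector("list", length(lines_keep))
    for (i in seq_along(lines_keep)) {
      ln <- lines_keep[i]
      rec <- tryCatch(jsonlite::fromJSON(lines[ln]),
                      error = function(e) {
                        stop(sprintf("malformed JSONL record on line %d: %s",
                                     ln, conditionMessage(e)))
                      })
      for (f in c("id", "author_id", "text")) {
        if (is.null(rec[[f]])) {
          stop(sprintf("record on line %d is missing field '%s'", ln, f))
        }
      }
      row <- lapply(setNames(CORPUS_FIELDS, CORPUS_FIELDS), function(f) {
        v <- rec[[f]]
        if (is.null(v) || length(v) == 0) NA_character_ else as.character(v)[1]
      })
      records[[i]] <- row
      if (i > 1 && row$id %in% vapply(records[seq_len(i - 1)], `[[`,
                                      character(1), "id")) {
        stop(sprintf("duplicate message id '%s' on line %d", row$id, ln))
      }
    }
    df <- if (length(records) == 0) {
      tibble(id = character(), author_id = character(), board_id = character(),
             timestamp = character(), text = character(),
             gold_label = character(), thread_id = character())
    } else {
      as_tibble(do.call(rbind.data.frame,
                        c(records, stringsAsFactors = FALSE)))
    }
  } else {
    df <- read.csv(path, colClasses = "character", check.names = FALSE,
                   encoding = "UTF-8")
    missing <- setdiff(c("id", "author_id", "text"), names(df))
    if (length(missing) > 0) {
      stop("CSV corpus lacks required column(s): ",
           paste(missing, collapse = ", "))
    }
    # CSV cannot distinguish empty strings from absent values; treat empties
    # as absent in the optional columns only
    for (f in c("board_id", "timestamp", "gold_label", "thread_id")) {
      if (f %in% names(df)) df[[f]][df[[f]] == ""] <- NA_character_
    }
    dup <- duplicated(df$id)
    if (any(dup)) {
      # +1 for the header row
      stop(sprintf("duplicate message id '%s' on line %d",
                   df$id[which(dup)[1]], which(dup)[1] + 1L))
    }
  }
  corpus(df, board_name = board_name, disease_type = disease_type)
}

#' Write a message corpus to JSONL or CSV
#'
#' Inverse of [read_corpus()]: a write/read round trip reproduces every
#' message field in the original order.
#'
#' @param corp a [corpus].
#' @param path output file path.
#' @param format `"jsonl"` or `"csv"`; default guessed from the extension.
#' @export
write_corpus <- function(corp, path, format = c("auto", "jsonl", "csv")) {
  stopifnot(inherits(corp, "corpus"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  msgs <- corp$messages
  if (format == "jsonl") {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(msgs))) {
      rec <- as.list(msgs[i, ])
      rec <- rec[!vapply(rec, is.na, logical(1))]
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"), con)
    }
  } else {
    out <- as.data.frame(msgs)
    out[is.na(out)] <- ""
    write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(NULL)
}

#' Summary statistics of a corpus
#'
#' Message count, distinct-member count, messages per member (rounded half-up
#' to 2 decimals, the presentation used in board summary tables), and the
#' observed time span.
#'
#' @param corp a [corpus], or alternatively `n_messages`/`n_members` counts to
#'   compute the ratio for a printed summary row without the raw messages.
#' @param n_messages,n_members optional explicit counts overriding `corp`.
#' @return a list of class `corpus_stats` with `n_messages`, `n_members`,
#'   `messages_per_member`, `time_span`.
#' @export
corpus_stats <- function(corp = NULL, n_messages = NULL, n_members = NULL) {
  time_span <- c(NA_character_, NA_character_)
  if (is.null(n_messages) || is.null(n_members)) {
    stopifnot(inherits(corp, "corpus"))
    if (nrow(corp$messages) == 0) {
      stop("corpus_stats is undefined for an empty corpus")
    }
    n_messages <- nrow(corp$messages)
    n_members <- length(unique(corp$messages$author_id))
    ts <- parse_timestamps(corp$messages$timestamp)
    if (any(!is.na(ts))) {
      time_span <- format(range(ts, na.rm = TRUE), "%Y-%m-%d")
    }
  }
  if (n_members < 1) stop("corpus_stats requires at least one member")
  structure(list(
    n_messages = as.integer(n_messages),
    n_members = as.integer(n_members),
    messages_per_member = round_half_up(n_messages / n_members, 2L),
    time_span = time_span
  ), class = "corpus_stats")
}

#' @export
print.corpus_stats <- function(x, ...) {
  cat(sprintf("messages: %d  members: %d  messages/member: %.2f\n",
              x$n_messages, x$n_members, x$messages_per_member))
  if (!anyNA(x$time_span)) {
    cat(sprintf("time span: %s to %s\n", x$time_span[1], x$time_span[2]))
  }
  invisible(x)
}

# round half away from zero at `digits` decimals (base round() is half-even)
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# lenient timestamp parsing: ISO date-times, then plain dates; unparseable
# values stay NA (stored raw in the corpus, excluded from time spans)
parse_timestamps <- function(x) {
  out <- as.Date(rep(NA_character_, length(x)))
  ok <- !is.na(x) & nzchar(x)
  if (!any(ok)) return(out)
  d <- suppressWarnings(as.Date(x[ok], format = "%Y-%m-%d"))
  dt <- suppressWarnings(as.Date(as.POSIXct(x[ok],
                                            format = "%Y-%m-%dT%H:%M:%S",
                                            tz = "UTC")))
  d[is.na(d)] <- dt[is.na(d)]
  out[ok] <- d
  out
}
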