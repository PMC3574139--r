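#' Porter stemmer
#'
#' Reduces English words to their stems with the Porter (1980) suffix-stripping
#' algorithm: five ordered rule groups, each applying the longest matching
#' suffix rule whose measure/vowel condition holds. Words shorter than three
#' letters are returned unchanged. Non-alphabetic characters are left intact,
#' so hyphenated tokens such as "x-ray" pass through with each alphabetic run
#' untouched unless it carries a strippable suffix.
#'
#' @param words character vector of lowercase words.
#' @return character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("coughing", "ponies", "relational", "blood"))
#' @export
porter_stem <- function(words) {
  stopifnot(is.character(words))
  if (length(words) == 0) return(character(0))
  u <- unique(words)
  stems <- vapply(u, porter_stem1, character(1), USE.NAMES = FALSE)
  stems[match(words, u)]
}

# --- internal single-word stemmer -----------------------------------------

porter_stem1 <- function(word) {
  if (is.na(word) || nchar(word) < 3L || !grepl("^[a-z]+$", word)) {
    return(word)
  }
  w <- word
  w <- porter_step1a(w)
  w <- porter_step1b(w)
  w <- porter_step1c(w)
  w <- porter_step2(w)
  w <- porter_step3(w)
  w <- porter_step4(w)
  w <- porter_step5(w)
  w
}

# consonant/vowel pattern: y is a vowel when preceded by a consonant
porter_cv <- function(w) {
  ch <- strsplit(w, "", fixed = TRUE)[[1]]
  n <- length(ch)
  out <- character(n)
  for (i in seq_len(n)) {
    c_i <- ch[i]
    if (c_i %in% c("a", "e", "i", "o", "u")) {
      out[i] <- "v"
    } else if (c_i == "y") {
      out[i] <- if (i == 1L || out[i - 1L] == "v") "c" else "v"
    } else {
      out[i] <- "c"
    }
  }
  out
}

# measure m in [C](VC)^m[V]
porter_m <- function(w) {
  if (nchar(w) == 0L) return(0L)
  cv <- porter_cv(w)
  runs <- rle(cv)$values
  sum(runs == "v") - as.integer(runs[length(runs)] == "v")
}

porter_has_vowel <- function(w) any(porter_cv(w) == "v")

porter_double_c <- function(w) {
  n <- nchar(w)
  if (n < 2L) return(FALSE)
  a <- substr(w, n - 1L, n - 1L); b <- substr(w, n, n)
  a == b && porter_cv(w)[n] == "c"
}

# *o: stem ends cvc where the final c is not w, x or y
porter_cvc <- function(w) {
  n <- nchar(w)
  if (n < 3L) return(FALSE)
  cv <- porter_cv(w)
  cv[n - 2L] == "c" && cv[n - 1L] == "v" && cv[n] == "c" &&
    !(substr(w, n, n) %in% c("w", "x", "y"))
}

ends_with <- function(w, suf) {
  n <- nchar(w); k <- nchar(suf)
  n > k && substr(w, n - k + 1L, n) == suf
}

drop_suffix <- function(w, suf) substr(w, 1L, nchar(w) - nchar(suf))

porter_step1a <- function(w) {
  if (ends_with(w, "sses")) return(drop_suffix(w, "es"))
  if (ends_with(w, "ies"))  return(drop_suffix(w, "es"))
  if (ends_with(w, "ss"))   return(w)
  if (ends_with(w, "s"))    return(drop_suffix(w, "s"))
  w
}

porter_step1b <- function(w) {
  if (ends_with(w, "eed")) {
    stem <- drop_suffix(w, "eed")
    if (porter_m(stem) > 0L) return(paste0(stem, "ee"))
    return(w)
  }
  applied <- FALSE
  if (ends_with(w, "ed")) {
    stem <- drop_suffix(w, "ed")
    if (porter_has_vowel(stem)) { w <- stem; applied <- TRUE }
  } else if (ends_with(w, "ing")) {
    stem <- drop_suffix(w, "ing")
    if (porter_has_vowel(stem)) { w <- stem; applied <- TRUE }
  }
  if (applied) {
    if (ends_with(w, "at") || ends_with(w, "bl") || ends_with(w, "iz")) {
      w <- paste0(w, "e")
    } else if (porter_double_c(w) &&
               !substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z")) {
      w <- substr(w, 1L, nchar(w) - 1L)
    } else if (porter_m(w) == 1L && porter_cvc(w)) {
      w <- paste0(w, "e")
    }
  }
  w
}

porter_step1c <- function(w) {
  if (ends_with(w, "y") && porter_has_vowel(drop_suffix(w, "y"))) {
    return(paste0(drop_suffix(w, "y"), "i"))
  }
  w
}

# rule tables for steps 2-4; longest matching suffix wins, then the
# measure condition on the remaining stem is tested
porter_rules <- function(w, rules, cond) {
  sufs <- names(rules)
  sufs <- sufs[order(-nchar(sufs))]
  for (suf in sufs) {
    if (ends_with(w, suf)) {
      stem <- drop_suffix(w, suf)
      if (cond(stem, suf)) return(paste0(stem, rules[[suf]]))
      return(w)
    }
  }
  w
}

porter_step2 <- function(w) {
  rules <- c(
    ational = "ate", tional = "tion", enci = "ence", anci = "ance",
    izer = "ize", abli = "able", alli = "al", entli = "ent", eli = "e",
    ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
    alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
    aliti = "al", iviti = "ive", biliti = "ble"
  )
  porter_rules(w, rules, function(stem, suf) porter_m(stem) > 0L)
}

porter_step3 <- function(w) {
  rules <- c(
    icate = "ic", ative = "", alize = "al", iciti = "ic",
    ical = "ic", ful = "", ness = ""
  )
  porter_rules(w, rules, function(stem, suf) porter_m(stem) > 0L)
}

porter_step4 <- function(w) {
  rules <- c(
    al = "", ance = "", ence = "", er = "", ic = "", able = "", ible = "",
    ant = "", ement = "", ment = "", ent = "", ion = "", ou = "", ism = "",
    ate = "", iti = "", ous = "", ive = "", ize = ""
  )
  cond <- function(stem, suf) {
    if (porter_m(stem) <= 1L) return(FALSE)
    if (suf == "ion") {
      last <- substr(stem, nchar(stem), nchar(stem))
      return(last %in% c("s", "t"))
    }
    TRUE
  }
  porter_rules(w, rules, cond)
}

porter_step5 <- function(w) {
  # 5a
  if (ends_with(w, "e")) {
    stem <- drop_suffix(w, "e")
    m <- porter_m(stem)
    if (m > 1L || (m == 1L && !porter_cvc(stem))) w <- stem
  }
  # 5b
  if (porter_m(w) > 1L && porter_double_c(w) &&
      substr(w, nchar(w), nchar(w)) == "l") {
    w <- substr(w, 1L, nchar(w) - 1L)
  }
  w
}
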