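# Porter stemming algorithm (Porter 1980), including the author's later
# "logi" -> "log" revision.  Implemented here because no stemming library
# ships with the package's dependency set; used by the name-composition
# analytics.

.p_classes <- function(chars) {
  # consonant/vowel classification; "y" is a vowel when preceded by a
  # consonant (or rather: consonant at start or after a vowel)
  n <- length(chars)
  cls <- character(n)
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch %in% c("a", "e", "i", "o", "u")) {
      cls[i] <- "v"
    } else if (ch == "y") {
      cls[i] <- if (i == 1 || cls[i - 1] == "v") "c" else "v"
    } else {
      cls[i] <- "c"
    }
  }
  cls
}

.p_measure <- function(stem) {
  if (!nchar(stem)) return(0L)
  cls <- .p_classes(strsplit(stem, "")[[1]])
  runs <- rle(cls)$values
  sum(runs[-1] == "c")  # count v->c alternations = VC sequences
}

.p_has_vowel <- function(stem) {
  nchar(stem) > 0 && any(.p_classes(strsplit(stem, "")[[1]]) == "v")
}

.p_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2) return(FALSE)
  a <- substr(word, n - 1, n - 1); b <- substr(word, n, n)
  a == b && .p_classes(strsplit(word, "")[[1]])[n] == "c"
}

.p_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3) return(FALSE)
  cls <- .p_classes(strsplit(word, "")[[1]])
  last <- substr(word, n, n)
  cls[n] == "c" && cls[n - 1] == "v" && cls[n - 2] == "c" &&
    !last %in% c("w", "x", "y")
}

.p_replace <- function(word, suffix, repl, min_m) {
  if (!endsWith(word, suffix)) return(NULL)
  stem <- substr(word, 1, nchar(word) - nchar(suffix))
  if (.p_measure(stem) > min_m - 1) paste0(stem, repl) else NULL
}

#' Porter stemmer
#'
#' Reduces English words to stems with the classic five-step suffix
#' stripping algorithm ("databases" and "database" both become "databas").
#' Vectorised; words of one or two characters are returned unchanged, and
#' case is lowered first.
#'
#' @param words Character vector.
#' @return Character vector of stems.
#' @examples
#' porter_stem(c("databases", "ontology", "relational", "analysis"))
#' @export
porter_stem <- function(words) {
  vapply(tolower(words), .porter_one, character(1), USE.NAMES = FALSE)
}

.porter_one <- function(w) {
  if (nchar(w) <= 2 || grepl("[^a-z]", w)) return(w)

  # step 1a
  if (endsWith(w, "sses")) w <- sub("sses$", "ss", w)
  else if (endsWith(w, "ies")) w <- sub("ies$", "i", w)
  else if (!endsWith(w, "ss") && endsWith(w, "s")) w <- sub("s$", "", w)

  # step 1b
  if (endsWith(w, "eed")) {
    stem <- sub("eed$", "", w)
    if (.p_measure(stem) > 0) w <- paste0(stem, "ee")
  } else {
    hit <- FALSE
    for (sfx in c("ed", "ing")) {
      if (endsWith(w, sfx)) {
        stem <- substr(w, 1, nchar(w) - nchar(sfx))
        if (.p_has_vowel(stem)) { w <- stem; hit <- TRUE }
        break
      }
    }
    if (hit) {
      if (endsWith(w, "at") || endsWith(w, "bl") || endsWith(w, "iz")) {
        w <- paste0(w, "e")
      } else if (.p_double_cons(w) &&
                 !substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z")) {
        w <- substr(w, 1, nchar(w) - 1)
      } else if (.p_measure(w) == 1 && .p_cvc(w)) {
        w <- paste0(w, "e")
      }
    }
  }

  # step 1c
  if (endsWith(w, "y") && .p_has_vowel(substr(w, 1, nchar(w) - 1))) {
    w <- sub("y$", "i", w)
  }

  # step 2 (longest matching suffix only)
  s2 <- c(ational = "ate", tional = "tion", enci = "ence", anci = "ance",
          izer = "ize", abli = "able", alli = "al", entli = "ent", eli = "e",
          ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
          alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
          aliti = "al", iviti = "ive", biliti = "ble", logi = "log")
  for (sfx in names(s2)[order(-nchar(names(s2)))]) {
    if (endsWith(w, sfx)) {
      r <- .p_replace(w, sfx, s2[[sfx]], 1L)
      if (!is.null(r)) w <- r
      break
    }
  }

  # step 3
  s3 <- c(icate = "ic", ative = "", alize = "al", iciti = "ic",
          ical = "ic", ful = "", ness = "")
  for (sfx in names(s3)[order(-nchar(names(s3)))]) {
    if (endsWith(w, sfx)) {
      r <- .p_replace(w, sfx, s3[[sfx]], 1L)
      if (!is.null(r)) w <- r
      break
    }
  }

  # step 4
  s4 <- c("ement", "ance", "ence", "able", "ible", "ment", "ant", "ent",
          "ism", "ate", "iti", "ous", "ive", "ize", "ion", "al", "er", "ic",
          "ou")
  for (sfx in s4[order(-nchar(s4))]) {
    if (endsWith(w, sfx)) {
      stem <- substr(w, 1, nchar(w) - nchar(sfx))
      if (.p_measure(stem) > 1) {
        if (sfx == "ion" &&
            !substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t")) break
        w <- stem
      }
      break
    }
  }

  # step 5a
  if (endsWith(w, "e")) {
    stem <- substr(w, 1, nchar(w) - 1)
    m <- .p_measure(stem)
    if (m > 1 || (m == 1 && !.p_cvc(stem))) w <- stem
  }
  # step 5b
  if (.p_measure(w) > 1 && .p_double_cons(w) && endsWith(w, "l")) {
    w <- substr(w, 1, nchar(w) - 1)
  }
  w
}
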