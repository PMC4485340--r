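# Rule-based clue detectors: explicit head terms, Hearst enumerations,
# title patterns, version strings, reference/URL adjacency and comparison
# cues, plus the clue-mention sentence co-occurrence statistic.

.HEAD_TERMS <- c("database", "software", "tool", "program", "simulator",
                 "system", "library", "service")

# Capitalised function words never treated as name candidates.
.NAME_STOP <- c("the", "a", "an", "in", "on", "of", "we", "this", "that",
                "these", "those", "it", "its", "our", "using", "with", "and",
                "or", "for", "to", "like", "both", "each", "all", "as")

# "Name-shaped": capitalised, all-caps, mixed-case with an internal
# capital, or letters with attached digits; never a stop word or a bare
# number.  A single lower-case letter counts when it abuts a name-shaped
# token (e.g. the "i" of "i Linker").
.name_shaped <- function(token) {
  shaped <- grepl("^[A-Z][A-Za-z0-9]*$", token) |          # Capitalised / CamelCase
    grepl("^[A-Z0-9]{2,}$", token) & grepl("[A-Z]", token) | # ALLCAPS / with digits
    grepl("^[a-z]+[A-Z][A-Za-z0-9]*$", token) |            # xPedPhase
    (grepl("[A-Za-z]", token) & grepl("[0-9]", token) & grepl("^[A-Za-z0-9]+$", token))
  shaped & !tolower(token) %in% .NAME_STOP & !grepl("^[0-9.]+$", token)
}

# Maximal run of name-shaped tokens (<= max_len) starting at `from` and
# moving in `dir` (+1 forward, -1 backward) within one sentence.  Returns
# token indices in document order, or integer(0).
.name_run <- function(tokens, from, dir, max_len = 4L) {
  n <- nrow(tokens)
  idx <- integer(0)
  i <- from
  while (i >= 1 && i <= n && length(idx) < max_len &&
         tokens$sent[i] == tokens$sent[from]) {
    ok <- .name_shaped(tokens$text[i])
    if (!ok && dir < 0 && grepl("^[a-z]$", tokens$text[i]) &&
        length(idx) > 0) ok <- TRUE   # "i" of "i Linker", scanning back
    if (!ok && dir > 0 && grepl("^[a-z]$", tokens$text[i]) &&
        i < n && .name_shaped(tokens$text[i + 1]) &&
        tokens$sent[i + 1] == tokens$sent[from]) ok <- TRUE
    if (!ok) break
    idx <- c(idx, i)
    i <- i + dir
  }
  sort(idx)
}

.clue_row <- function(tokens, doc_id, category, clue_idx, cand_idx, text) {
  span <- function(idx) {
    if (!length(idx)) return(list(start = NA_integer_, end = NA_integer_, s = NA_character_))
    list(start = tokens$start[min(idx)], end = tokens$end[max(idx)],
         s = substr(text, tokens$start[min(idx)] + 1L, tokens$end[max(idx)]))
  }
  cl <- span(clue_idx); cd <- span(cand_idx)
  tibble::tibble(doc_id = doc_id, sent = tokens$sent[min(c(clue_idx, cand_idx))],
                 category = category,
                 clue_start = cl$start, clue_end = cl$end, clue = cl$s,
                 cand_start = cd$start, cand_end = cd$end, candidate = cd$s)
}

.empty_clues <- function() {
  tibble::tibble(doc_id = character(), sent = integer(), category = character(),
                 clue_start = integer(), clue_end = integer(), clue = character(),
                 cand_start = integer(), cand_end = integer(),
                 candidate = character())
}

#' Detect head-term clues
#'
#' Emits a clue for every head term (database, software, tool, program,
#' simulator, system, library, service); the candidate is the adjacent
#' name-shaped token run on the non-head side when one exists — following
#' the head ("the stochastic simulator Dizzy") or preceding it ("The
#' MethMarker software").
#'
#' @param tokens Token tibble for one document.
#' @param text Document text.
#' @param doc_id Document id.
#' @return A clue tibble (`category = "head"`); `candidate` is `NA` when no
#'   name-shaped neighbour exists.
#' @export
detect_head_terms <- function(tokens, text, doc_id = "doc") {
  heads <- which(tolower(tokens$text) %in% .HEAD_TERMS)
  if (!length(heads)) return(.empty_clues())
  purrr::map_dfr(heads, function(h) {
    cand <- .name_run(tokens, h + 1L, +1L)
    if (!length(cand)) cand <- .name_run(tokens, h - 1L, -1L)
    .clue_row(tokens, doc_id, "head", h, cand, text)
  })
}

#' Detect Hearst enumeration clues
#'
#' Patterns `<head>s: A, B, ..., and C` and `<head>s such as A, ..., and C`
#' yield every name-shaped list member as a candidate.
#'
#' @inheritParams detect_head_terms
#' @return A clue tibble (`category = "hearst"`), one row per list member.
#' @export
detect_hearst <- function(tokens, text, doc_id = "doc") {
  n <- nrow(tokens)
  heads <- which(tolower(tokens$text) %in% paste0(.HEAD_TERMS, "s"))
  if (!length(heads)) return(.empty_clues())
  out <- list()
  for (h in heads) {
    # find the start of the enumeration
    pos <- NULL
    if (h < n && tokens$text[h + 1] == ":") pos <- h + 2L
    if (is.null(pos) && h + 2 <= n &&
        tolower(tokens$text[h + 1]) == "such" &&
        tolower(tokens$text[h + 2]) == "as") pos <- h + 3L
    if (is.null(pos)) next
    members <- list()
    while (pos <= n && tokens$sent[pos] == tokens$sent[h]) {
      tk <- tokens$text[pos]
      if (tk %in% c(",", "…") || tolower(tk) == "and" || tk == ".") {
        pos <- pos + 1L
        if (tk == ".") break
        next
      }
      run <- .name_run(tokens, pos, +1L)
      if (!length(run)) break
      members[[length(members) + 1L]] <- run
      pos <- max(run) + 1L
    }
    for (m in members) {
      out[[length(out) + 1L]] <- .clue_row(tokens, doc_id, "hearst", h, m, text)
    }
  }
  if (!length(out)) return(.empty_clues())
  dplyr::bind_rows(out)
}

#' Detect the new-resource title pattern
#'
#' Titles of papers introducing a resource typically read
#' `"<Name>: <description>"`.  Returns the pre-colon name when it is at
#' most four tokens, every token is name-shaped, and the pre-colon text
#' does not contain "method" or "algorithm" (titles matching the pattern
#' but introducing a method are rejected).
#'
#' @param title Title string.
#' @return The candidate name, or `NA_character_`.
#' @examples
#' detect_title_pattern("CoXpress: differential co-expression in gene expression data")
#' @export
detect_title_pattern <- function(title) {
  if (is.na(title) || !nzchar(title) || !grepl(":", title, fixed = TRUE)) {
    return(NA_character_)
  }
  pre <- trimws(sub(":.*$", "", title))
  if (!nzchar(pre)) return(NA_character_)
  if (grepl("\\b(method|algorithm)s?\\b", tolower(pre))) return(NA_character_)
  toks <- strsplit(pre, "\\s+")[[1]]
  if (length(toks) > 4) return(NA_character_)
  if (!all(.name_shaped(toks))) return(NA_character_)
  pre
}

.VERSION_UNITS <- c("ghz", "mhz", "hz", "mb", "gb", "kb", "tb", "bp", "kbp",
                    "%", "s", "ms", "h", "gbp")

#' Detect versioning clues
#'
#' Patterns `<Name> v<digits>`, `<Name> version <number>` and the bare
#' `<Name> <number.number>` form; the bare form is suppressed when the
#' number is followed by a unit token (GHz, MB, %, ...), so hardware specs
#' like "AMD Athlon 1.8 GHz" yield no candidate.
#'
#' @inheritParams detect_head_terms
#' @return A clue tibble (`category = "version"`); `clue` holds the version
#'   string.
#' @export
detect_version <- function(tokens, text, doc_id = "doc") {
  n <- nrow(tokens)
  out <- list()
  for (i in seq_len(n)) {
    tk <- tokens$text[i]
    ver <- NULL; vi <- i
    if (grepl("^[vV][0-9]+(\\.[0-9]+)*$", tk)) {
      ver <- sub("^[vV]", "", tk)
    } else if (tolower(tk) == "version" && i < n &&
               grepl("^[0-9]+(\\.[0-9]+)*$", tokens$text[i + 1])) {
      ver <- tokens$text[i + 1]; vi <- i + 1L
    } else if (grepl("^[0-9]+\\.[0-9.]+$", tk)) {
      nxt <- if (i < n && tokens$sent[i + 1] == tokens$sent[i])
        tolower(tokens$text[i + 1]) else ""
      if (nxt %in% .VERSION_UNITS) next
      ver <- tk
    }
    if (is.null(ver)) next
    cand <- .name_run(tokens, i - 1L, -1L)
    explicit <- grepl("^[vV]", tk) || tolower(tk) == "version"
    if (!length(cand) && explicit && i > 1) {
      # an explicit v/version marker is unambiguous; accept the preceding
      # plain word ("using dot v1.10") when no name-shaped run exists
      prev <- tokens$text[i - 1]
      if (grepl("^[A-Za-z][A-Za-z0-9]*$", prev) &&
          !tolower(prev) %in% .NAME_STOP) cand <- i - 1L
    }
    if (!length(cand)) next
    out[[length(out) + 1L]] <-
      dplyr::mutate(.clue_row(tokens, doc_id, "version", vi, cand, text),
                    clue = ver)
  }
  if (!length(out)) return(.empty_clues())
  dplyr::bind_rows(out)
}

#' Detect reference / URL adjacency clues
#'
#' A name-shaped token run immediately before a `[digits]` citation marker
#' or a URL becomes a candidate ("Galaxy [18] and EpiGRAPH [19]").
#' Lower-case common words before a citation are rejected by the
#' name-shape filter.
#'
#' @inheritParams detect_head_terms
#' @return A clue tibble (`category = "ref_url"`).
#' @export
detect_ref_url <- function(tokens, text, doc_id = "doc") {
  n <- nrow(tokens)
  out <- list()
  for (i in seq_len(n)) {
    is_ref <- FALSE
    if (tokens$text[i] == "[" && i + 1 <= n &&
        grepl("^[0-9]+$", tokens$text[i + 1])) {
      is_ref <- TRUE
    } else if (grepl("^(https?://|www\\.)", tokens$text[i])) {
      is_ref <- TRUE
    }
    if (!is_ref) next
    cand <- .name_run(tokens, i - 1L, -1L)
    if (!length(cand)) next
    out[[length(out) + 1L]] <- .clue_row(tokens, doc_id, "ref_url", i, cand, text)
  }
  if (!length(out)) return(.empty_clues())
  dplyr::bind_rows(out)
}

.COMPARISON_CUES <- list(c("better", "than"), c("compared", "to"),
                         c("slower", "than"), c("faster", "than"),
                         c("equal", "to"))

#' Detect comparison clues
#'
#' Comparison cues ("better than", "compared to", "slower/faster than",
#' "equal to") with name-shaped runs on both sides yield a candidate pair,
#' as does the extended pattern "Like X, Y ...".
#'
#' @inheritParams detect_head_terms
#' @return A clue tibble (`category = "comparison"`); the pair is reported
#'   as `candidate` (left) and `candidate2` (right).
#' @export
detect_comparison <- function(tokens, text, doc_id = "doc") {
  n <- nrow(tokens)
  out <- list()
  find_near <- function(from, dir) {
    i <- from
    while (i >= 1 && i <= n && tokens$sent[i] == tokens$sent[from]) {
      run <- .name_run(tokens, i, dir)
      if (length(run)) return(run)
      i <- i + dir
    }
    integer(0)
  }
  for (i in seq_len(max(0, n - 1))) {
    for (cue in .COMPARISON_CUES) {
      if (tolower(tokens$text[i]) == cue[1] &&
          tolower(tokens$text[i + 1]) == cue[2]) {
        left <- find_near(i - 1L, -1L)
        right <- find_near(i + 2L, +1L)
        if (length(left) && length(right)) {
          row <- .clue_row(tokens, doc_id, "comparison", c(i, i + 1L), left, text)
          row$candidate2 <- substr(text, tokens$start[min(right)] + 1L,
                                   tokens$end[max(right)])
          out[[length(out) + 1L]] <- row
        }
      }
    }
    if (tolower(tokens$text[i]) == "like" &&
        (i == 1 || tokens$sent[i - 1] != tokens$sent[i])) {
      run1 <- .name_run(tokens, i + 1L, +1L)
      if (length(run1) && max(run1) + 2 <= n &&
          tokens$text[max(run1) + 1] == ",") {
        run2 <- .name_run(tokens, max(run1) + 2L, +1L)
        if (length(run2)) {
          row <- .clue_row(tokens, doc_id, "comparison", i, run1, text)
          row$candidate2 <- substr(text, tokens$start[min(run2)] + 1L,
                                   tokens$end[max(run2)])
          out[[length(out) + 1L]] <- row
        }
      }
    }
  }
  if (!length(out)) {
    e <- .empty_clues(); e$candidate2 <- character(); return(e)
  }
  dplyr::bind_rows(out)
}

#' Run every clue detector over a corpus
#'
#' @param corpus Corpus tibble.
#' @return Combined clue tibble; title-pattern hits appear with
#'   `category = "title"` and the candidate only.
#' @export
detect_clues <- function(corpus) {
  purrr::map_dfr(seq_len(nrow(corpus)), function(i) {
    toks <- corpus$tokens[[i]]
    d <- corpus$doc_id[i]
    txt <- corpus$text[i]
    res <- dplyr::bind_rows(
      detect_head_terms(toks, txt, d),
      detect_hearst(toks, txt, d),
      detect_version(toks, txt, d),
      detect_ref_url(toks, txt, d),
      detect_comparison(toks, txt, d)
    )
    tc <- detect_title_pattern(corpus$title[i])
    if (!is.na(tc)) {
      res <- dplyr::bind_rows(res, tibble::tibble(
        doc_id = d, sent = NA_integer_, category = "title",
        clue_start = NA_integer_, clue_end = NA_integer_, clue = corpus$title[i],
        cand_start = NA_integer_, cand_end = NA_integer_, candidate = tc))
    }
    res
  })
}

#' Clue-mention sentence co-occurrence
#'
#' For a clue regular expression, counts the sentences matching it and the
#' fraction that also contain a gold mention (forward), and conversely the
#' fraction of mention-bearing sentences that match the clue (reverse).
#' Quantifies how discriminative a candidate clue word is.
#'
#' @param corpus Corpus tibble.
#' @param mentions Gold mention tibble.
#' @param regex Perl-compatible regular expression (e.g.
#'   `"ran|run(ning|s)?"`).
#' @param ignore_case Case-insensitive matching (default `TRUE`).
#' @return One-row tibble: `regex`, `n_clue_sentences`,
#'   `n_clue_sentences_with_mention`, `forward_fraction`,
#'   `n_mention_sentences`, `n_mention_sentences_with_clue`,
#'   `reverse_fraction`, `no_match` flag.
#' @export
clue_cooccurrence <- function(corpus, mentions, regex, ignore_case = TRUE) {
  sent_rows <- purrr::map_dfr(seq_len(nrow(corpus)), function(i) {
    toks <- corpus$tokens[[i]]
    if (!nrow(toks)) return(NULL)
    d <- corpus$doc_id[i]
    m <- mentions[mentions$doc_id == d, ]
    toks |>
      dplyr::group_by(.data$sent) |>
      dplyr::summarise(s = min(.data$start), e = max(.data$end), .groups = "drop") |>
      dplyr::mutate(
        text = substring(corpus$text[i], .data$s + 1L, .data$e),
        has_mention = purrr::map2_lgl(.data$s, .data$e, function(s, e) {
          any(.overlaps(m$start, m$end, s, e))
        }))
  })
  hit <- grepl(regex, sent_rows$text, perl = TRUE, ignore.case = ignore_case)
  n_clue <- sum(hit)
  n_clue_m <- sum(hit & sent_rows$has_mention)
  n_m <- sum(sent_rows$has_mention)
  n_m_clue <- sum(hit & sent_rows$has_mention)
  tibble::tibble(
    regex = regex,
    n_clue_sentences = n_clue,
    n_clue_sentences_with_mention = n_clue_m,
    forward_fraction = if (n_clue == 0) 0 else n_clue_m / n_clue,
    n_mention_sentences = n_m,
    n_mention_sentences_with_clue = n_m_clue,
    reverse_fraction = if (n_m == 0) 0 else n_m_clue / n_m,
    no_match = n_clue == 0
  )
}
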