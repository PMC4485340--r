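# Resource-name dictionary: construction, normalisation, leftmost-longest
# matching on token boundaries, abbreviation expansion and ambiguity
# reporting.

.norm_ws <- function(x) gsub("\\s+", " ", trimws(x))

#' Build a resource dictionary from a data frame
#'
#' @param entries Data frame with columns `canonical`, `rtype`
#'   (`DB`/`SW`/`PK`), `source` and `variants` — either a list-column of
#'   character vectors or a pipe-separated string per row.  The canonical
#'   name is always included among the variants.
#' @return A `resource_dictionary`: list with `entries` (tibble `entry_id`,
#'   `canonical`, `rtype`, `source`) and `variants` (tibble `entry_id`,
#'   `variant`, `norm`).  Duplicate variants across entries are retained —
#'   each remains resolvable — and flagged ambiguous by the matcher when the
#'   owning entries disagree on type.
#' @examples
#' d <- new_dictionary(tibble::tibble(
#'   canonical = "UniProt", rtype = "DB", source = "demo",
#'   variants = "UniProt|Uniprot"))
#' dictionary_stats(d)
#' @export
new_dictionary <- function(entries) {
  stopifnot(is.data.frame(entries),
            all(c("canonical", "rtype") %in% names(entries)))
  n <- nrow(entries)
  canonical <- .norm_ws(as.character(entries$canonical))
  rtype <- as.character(entries$rtype)
  bad <- which(!rtype %in% c("DB", "SW", "PK"))
  if (length(bad)) {
    stop(sprintf("entry %d (%s): unknown rtype code %s",
                 bad[1], canonical[bad[1]], dQuote(rtype[bad[1]])), call. = FALSE)
  }
  bad <- which(!nzchar(canonical))
  if (length(bad)) stop(sprintf("entry %d: blank canonical name", bad[1]), call. = FALSE)
  src <- if ("source" %in% names(entries)) as.character(entries$source) else "unknown"
  vr <- if ("variants" %in% names(entries)) entries$variants else vector("list", n)
  var_list <- purrr::map(seq_len(n), function(i) {
    v <- vr[[i]]
    if (is.null(v) || all(is.na(v))) v <- character()
    if (is.character(v) && length(v) == 1 && grepl("|", v, fixed = TRUE)) {
      v <- strsplit(v, "|", fixed = TRUE)[[1]]
    }
    v <- .norm_ws(v)
    unique(c(canonical[i], v[nzchar(v)]))
  })
  variants <- tibble::tibble(
    entry_id = rep(seq_len(n), lengths(var_list)),
    variant = as.character(unlist(var_list, use.names = FALSE))
  )
  variants$norm <- tolower(variants$variant)
  structure(
    list(entries = tibble::tibble(entry_id = seq_len(n), canonical = canonical,
                                  rtype = rtype, source = src),
         variants = variants),
    class = "resource_dictionary"
  )
}

#' Read a dictionary TSV
#'
#' Tab-separated columns `canonical`, `rtype`, `source`, `variants`
#' (pipe-separated; may be empty).  A header line is detected and skipped.
#'
#' @param path File path.
#' @return A `resource_dictionary`.
#' @export
read_dictionary <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(new_dictionary(tibble::tibble(canonical = character(), rtype = character())))
  if (grepl("^canonical\t", lines[1])) lines <- lines[-1]
  if (!length(lines)) return(new_dictionary(tibble::tibble(canonical = character(), rtype = character())))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2)
  if (length(bad)) stop(sprintf("%s line %d: expected at least 2 tab-separated columns",
                                path, bad[1]), call. = FALSE)
  df <- tibble::tibble(
    canonical = purrr::map_chr(parts, 1),
    rtype = purrr::map_chr(parts, 2),
    source = purrr::map_chr(parts, ~ if (length(.x) >= 3) .x[[3]] else "unknown"),
    variants = purrr::map_chr(parts, ~ if (length(.x) >= 4) .x[[4]] else "")
  )
  tryCatch(new_dictionary(df), error = function(e) {
    stop(sprintf("%s: %s", path, conditionMessage(e)), call. = FALSE)
  })
}

#' @rdname read_dictionary
#' @param dict A `resource_dictionary`.
#' @export
write_dictionary <- function(dict, path) {
  v <- split(dict$variants$variant, dict$variants$entry_id)
  lines <- sprintf("%s\t%s\t%s\t%s",
                   dict$entries$canonical, dict$entries$rtype, dict$entries$source,
                   purrr::map_chr(v[as.character(dict$entries$entry_id)],
                                  paste, collapse = "|"))
  writeLines(c("canonical\trtype\tsource\tvariants", lines), path)
  invisible(path)
}

#' Dictionary summary counts
#'
#' Counts entries, variant instances (one per entry-variant pair) and unique
#' variants after whitespace normalisation — the deduplication used when
#' quoting dictionary-level variability.
#'
#' @param dict A `resource_dictionary`.
#' @return A one-row tibble: `n_entries`, `n_variants`, `n_unique_variants`.
#' @export
dictionary_stats <- function(dict) {
  tibble::tibble(
    n_entries = nrow(dict$entries),
    n_variants = nrow(dict$variants),
    n_unique_variants = length(unique(dict$variants$variant))
  )
}

#' @export
print.resource_dictionary <- function(x, ...) {
  s <- dictionary_stats(x)
  cat(sprintf("<resource_dictionary> %d entries, %d variants (%d unique)\n",
              s$n_entries, s$n_variants, s$n_unique_variants))
  invisible(x)
}

# Case policy: short (<= 4 chars) or all-caps variants match case-sensitively
# only; longer mixed-case variants also match case-insensitively.  Keeps
# acronyms like "GO" from matching "go" while tolerating case drift in long
# names ("Gene ontology").
.case_sensitive_variant <- function(variant) {
  nchar(variant) <= 4 | variant == toupper(variant)
}

#' Match dictionary names in a document
#'
#' Leftmost-longest, non-overlapping matching of dictionary variants against
#' token-boundary spans.  A candidate immediately followed by `:` + digits
#' is suppressed when `suppress_identifiers = TRUE` (default), so database
#' names cannot match inside record identifiers such as `GO:0007089`.  When
#' `expand_abbreviations = TRUE`, Schwartz–Hearst pairs whose long form
#' matches the dictionary add their short form as a document-local variant
#' and matching runs a second pass.
#'
#' @param tokens Token tibble for one document.
#' @param dict A `resource_dictionary`.
#' @param text Document text.
#' @param doc_id Document id stamped on the mentions.
#' @param suppress_identifiers Suppress matches followed by `:` + digits.
#' @param expand_abbreviations Add document-local short forms (see
#'   [detect_abbreviations()]).
#' @param max_tokens Longest variant length considered, in tokens.
#' @return A mention tibble with `source = "dictionary"`; `rtype` is the
#'   owning entry's type (`DATABASE`/`SOFTWARE`) or `UNSPECIFIED` when a
#'   variant belongs to several entries of different types.
#' @export
match_dictionary <- function(tokens, dict, text, doc_id = "doc",
                             suppress_identifiers = TRUE,
                             expand_abbreviations = FALSE,
                             max_tokens = 10L) {
  variants <- dict$variants
  if (expand_abbreviations && nrow(variants)) {
    pairs <- detect_abbreviations(tokens, text)
    if (nrow(pairs)) {
      lf <- .norm_ws(pairs$long_form)
      hit <- match(tolower(lf), variants$norm)
      ok <- !is.na(hit)
      if (any(ok)) {
        extra <- tibble::tibble(entry_id = variants$entry_id[hit[ok]],
                                variant = pairs$short_form[ok],
                                norm = tolower(pairs$short_form[ok]))
        variants <- dplyr::bind_rows(variants, extra)
      }
    }
  }
  .match_variants(tokens, variants, dict$entries, text, doc_id,
                  suppress_identifiers, max_tokens)
}

.match_variants <- function(tokens, variants, entries, text, doc_id,
                            suppress_identifiers, max_tokens) {
  if (!nrow(tokens) || !nrow(variants)) return(.mention_cols())
  norm_index <- split(seq_len(nrow(variants)), variants$norm)
  n <- nrow(tokens)
  out <- list()
  i <- 1L
  while (i <= n) {
    best <- NULL
    jmax <- min(n, i + max_tokens - 1L)
    for (j in jmax:i) {
      if (tokens$sent[j] != tokens$sent[i]) next
      surface <- substr(text, tokens$start[i] + 1L, tokens$end[j])
      key <- tolower(.norm_ws(surface))
      cand <- norm_index[[key]]
      if (is.null(cand)) next
      v <- variants$variant[cand]
      cs <- .case_sensitive_variant(v)
      ok <- cand[(!cs) | v == .norm_ws(surface)]
      if (!length(ok)) next
      if (suppress_identifiers &&
          grepl("^:[0-9]", substr(text, tokens$end[j] + 1L, tokens$end[j] + 2L))) next
      ids <- unique(variants$entry_id[ok])
      ty <- unique(entries$rtype[match(ids, entries$entry_id)])
      rtype <- if (length(ty) == 1) switch(ty, DB = "DATABASE", "SOFTWARE")
               else "UNSPECIFIED"
      best <- list(start = tokens$start[i], end = tokens$end[j],
                   surface = surface, rtype = rtype, next_i = j + 1L)
      break  # j descends from longest, so first hit is the longest
    }
    if (is.null(best)) {
      i <- i + 1L
    } else {
      out[[length(out) + 1L]] <- best
      i <- best$next_i
    }
  }
  if (!length(out)) return(.mention_cols())
  tibble::tibble(
    doc_id = doc_id,
    start = purrr::map_int(out, "start"),
    end = purrr::map_int(out, "end"),
    surface = purrr::map_chr(out, "surface"),
    rtype = purrr::map_chr(out, "rtype"),
    source = "dictionary"
  )
}

#' Dictionary matching over a whole corpus
#'
#' @param corpus Corpus tibble.
#' @inheritParams match_dictionary
#' @return Mention tibble across all documents.
#' @export
match_corpus <- function(corpus, dict, suppress_identifiers = TRUE,
                         expand_abbreviations = FALSE, max_tokens = 10L) {
  purrr::map_dfr(seq_len(nrow(corpus)), function(i) {
    match_dictionary(corpus$tokens[[i]], dict, corpus$text[i], corpus$doc_id[i],
                     suppress_identifiers = suppress_identifiers,
                     expand_abbreviations = expand_abbreviations,
                     max_tokens = max_tokens)
  })
}

#' Detect "Long Form (SF)" abbreviation definitions
#'
#' Schwartz–Hearst-style pairing: for each parenthesised short-form
#' candidate (2–10 characters, at most two words, containing a letter), the
#' algorithm scans the preceding words right-to-left matching short-form
#' characters in order; the first character of the short form must start a
#' word of the long form.  Candidates like `(2 %)` fail the letter-overlap
#' test and yield no pair.
#'
#' @param tokens Token tibble for one document.
#' @param text Document text.
#' @return Tibble `long_start`, `long_end` (character offsets), `long_form`,
#'   `short_form`.
#' @examples
#' txt <- "the Database of Interacting Proteins (DIP) stores"
#' detect_abbreviations(tokenize_text(txt), txt)
#' @export
detect_abbreviations <- function(tokens, text) {
  empty <- tibble::tibble(long_start = integer(), long_end = integer(),
                          long_form = character(), short_form = character())
  opens <- which(tokens$text == "(")
  if (!length(opens)) return(empty)
  out <- list()
  for (o in opens) {
    close <- which(tokens$text == ")" & seq_len(nrow(tokens)) > o &
                   tokens$sent == tokens$sent[o])
    if (!length(close)) next
    c1 <- close[1]
    if (c1 - o < 2 || c1 - o > 3) next        # one or two tokens inside
    sf <- substr(text, tokens$end[o] + 1L, tokens$start[c1])
    sf <- trimws(sf)
    if (nchar(sf) < 2 || nchar(sf) > 10) next
    if (!grepl("[A-Za-z]", sf)) next
    if (lengths(regmatches(sf, gregexpr("\\s+", sf))) > 1) next
    # candidate long form: up to min(|sf|+5, 2|sf|) words before the paren
    max_words <- min(nchar(sf) + 5L, 2L * nchar(sf))
    word_idx <- which(seq_len(nrow(tokens)) < o &
                      tokens$sent == tokens$sent[o] &
                      grepl("[A-Za-z0-9]", tokens$text))
    if (!length(word_idx)) next
    word_idx <- utils::tail(word_idx, max_words)
    span <- .sh_pair(sf, tokens$text[word_idx])
    if (is.null(span)) next
    first <- word_idx[span]
    out[[length(out) + 1L]] <- tibble::tibble(
      long_start = tokens$start[first],
      long_end = tokens$end[word_idx[length(word_idx)]],
      long_form = substr(text, tokens$start[first] + 1L,
                         tokens$end[word_idx[length(word_idx)]]),
      short_form = sf
    )
  }
  if (!length(out)) return(empty)
  dplyr::distinct(dplyr::bind_rows(out))
}

# Schwartz-Hearst character alignment: match short-form characters
# right-to-left against the candidate words; returns the index (into
# `words`) where the long form starts, or NULL if no valid alignment.
.sh_pair <- function(sf, words) {
  sfl <- tolower(strsplit(sf, "")[[1]])
  sfl <- sfl[sfl != " "]
  long <- tolower(paste(words, collapse = " "))
  li <- nchar(long)
  si <- length(sfl)
  long_chars <- strsplit(long, "")[[1]]
  while (si > 0) {
    ch <- sfl[si]
    if (!grepl("[a-z0-9]", ch)) { si <- si - 1; next }
    while (li > 0 && (long_chars[li] != ch ||
                      (si == 1 && li > 1 && long_chars[li - 1] != " "))) {
      li <- li - 1
    }
    if (li == 0) return(NULL)
    si <- si - 1
    li <- li - 1
  }
  # position li+1 is the first matched char; find which word it starts in
  nch <- nchar(words)
  word_starts <- cumsum(c(1, nch[-length(nch)] + 1))
  w <- max(which(word_starts <= li + 1))
  w
}

#' Name-ambiguity report against word lists
#'
#' Intersects a set of resource names with plain word lists (for example a
#' common-English dictionary and a known-acronym list) to quantify how many
#' names collide with ordinary vocabulary.
#'
#' @param names Character vector of names, or a `resource_dictionary`
#'   (variants are used).
#' @param ... Named word lists: each a character vector or a path to a
#'   one-term-per-line UTF-8 file.
#' @param case_sensitive Compare exactly (`TRUE`, default) or lower-case
#'   both sides.
#' @return A tibble with one row per list: `list`, `n_names`, `n_overlap`
#'   and a `matches` list-column of the overlapping names.
#' @examples
#' ambiguity_report(c("analysis", "UniProt"), english = c("analysis", "cycle"))
#' @export
ambiguity_report <- function(names, ..., case_sensitive = TRUE) {
  if (inherits(names, "resource_dictionary")) names <- unique(names$variants$variant)
  names <- unique(names)
  lists <- list(...)
  stopifnot(length(lists) > 0, !is.null(names(lists)))
  purrr::imap_dfr(lists, function(words, nm) {
    if (is.character(words) && length(words) == 1 && file.exists(words)) {
      words <- readLines(words, warn = FALSE)
    }
    words <- words[nzchar(words)]
    a <- names
    b <- words
    if (!case_sensitive) { a <- tolower(a); b <- tolower(b) }
    hit <- unique(names[a %in% b])
    tibble::tibble(list = nm, n_names = length(names),
                   n_overlap = length(hit), matches = list(hit))
  })
}
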