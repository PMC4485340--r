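# B-I-O label handling: conversion between character-offset mentions and
# per-token label sequences, label repair, and CoNLL-style export.

#' Convert mentions to a B-I-O label sequence
#'
#' The first token of each mention is labelled `B`, subsequent tokens `I`,
#' all others `O`.  Mentions whose boundaries fall inside a token are
#' snapped outward to the covering tokens with a warning (never dropped, so
#' recall accounting is preserved).
#'
#' @param tokens Token tibble for one document ([tokenize_text()]).
#' @param mentions Mention tibble (rows for this document; non-overlapping).
#' @return Character vector of labels, one per token.
#' @examples
#' toks <- tokenize_text("used BLAST here")
#' mentions_to_bio(toks, new_mentions("d", 5, 10, "BLAST"))
#' @export
mentions_to_bio <- function(tokens, mentions) {
  labels <- rep("O", nrow(tokens))
  if (nrow(mentions) == 0) return(labels)
  m <- dplyr::arrange(mentions, .data$start)
  if (nrow(m) > 1 && any(m$start[-1] < m$end[-nrow(m)])) {
    stop("overlapping mentions cannot be encoded as B-I-O", call. = FALSE)
  }
  for (i in seq_len(nrow(m))) {
    idx <- which(tokens$end > m$start[i] & tokens$start < m$end[i])
    if (!length(idx)) {
      warning(sprintf("mention [%d,%d) covers no token; skipped",
                      m$start[i], m$end[i]))
      next
    }
    if (tokens$start[idx[1]] != m$start[i] || tokens$end[idx[length(idx)]] != m$end[i]) {
      warning(sprintf("mention [%d,%d) snapped outward to token span [%d,%d)",
                      m$start[i], m$end[i],
                      tokens$start[idx[1]], tokens$end[idx[length(idx)]]))
    }
    labels[idx[1]] <- "B"
    if (length(idx) > 1) labels[idx[-1]] <- "I"
  }
  labels
}

#' Convert a B-I-O label sequence back to mentions
#'
#' Maximal `B I*` runs become mentions.  Round-trips with
#' [mentions_to_bio()] for token-aligned, non-overlapping mentions.
#'
#' @param tokens Token tibble for one document.
#' @param labels Character vector of valid labels, one per token.
#' @param doc_id Document id stamped on the result.
#' @param text Document text, used to slice mention surfaces.
#' @param source Provenance recorded in the `source` column.
#' @return A mention tibble.
#' @export
bio_to_mentions <- function(tokens, labels, doc_id, text, source = "crf") {
  if (length(labels) != nrow(tokens)) {
    stop(sprintf("label sequence length %d != token count %d",
                 length(labels), nrow(tokens)), call. = FALSE)
  }
  if (!length(labels) || !any(labels != "O")) return(.mention_cols())
  starts <- which(labels == "B")
  out <- purrr::map_dfr(starts, function(s) {
    e <- s
    while (e < length(labels) && labels[e + 1] == "I") e <- e + 1L
    tibble::tibble(doc_id = doc_id,
                   start = tokens$start[s], end = tokens$end[e],
                   surface = substr(text, tokens$start[s] + 1L, tokens$end[e]),
                   rtype = "UNSPECIFIED", source = source)
  })
  dplyr::arrange(out, .data$start)
}

#' Repair an invalid B-I-O sequence
#'
#' Every `I` not preceded by `B` or `I` (including `I` at position one or at
#' a sentence start) becomes `B`.  Idempotent.
#'
#' @param labels Character vector over `{B, I, O}`.
#' @param sent Optional sentence index per token; when given, an `I` carried
#'   across a sentence boundary also becomes `B`.
#' @return A valid label vector of the same length.
#' @examples
#' repair_bio(c("O", "I", "I"))
#' @export
repair_bio <- function(labels, sent = NULL) {
  if (!length(labels)) return(labels)
  prev <- c("O", labels[-length(labels)])
  new_sent <- if (is.null(sent)) rep(FALSE, length(labels))
              else c(TRUE, sent[-1] != sent[-length(sent)])
  fix <- labels == "I" & (prev == "O" | new_sent)
  # a repaired I becomes B; following I tokens are then validly attached
  while (any(fix)) {
    labels[fix] <- "B"
    prev <- c("O", labels[-length(labels)])
    fix <- labels == "I" & (prev == "O" | new_sent)
  }
  labels
}

#' Corpus-level B-I-O labels
#'
#' Applies [mentions_to_bio()] to every document and returns a flat tibble.
#'
#' @param corpus Corpus tibble.
#' @param mentions Mention tibble.
#' @return Tibble `doc_id`, `token_id`, `label`.
#' @export
bio_labels <- function(corpus, mentions) {
  purrr::map_dfr(seq_len(nrow(corpus)), function(i) {
    d <- corpus$doc_id[i]
    tibble::tibble(
      doc_id = d,
      token_id = corpus$tokens[[i]]$token_id,
      label = mentions_to_bio(corpus$tokens[[i]],
                              mentions[mentions$doc_id == d, , drop = FALSE])
    )
  })
}

#' Corpus-level mentions from labels
#'
#' @param corpus Corpus tibble.
#' @param labels Flat label tibble (`doc_id`, `token_id`, `label`).
#' @param source Provenance stamped on the mentions.
#' @return Mention tibble.
#' @export
labels_to_mentions <- function(corpus, labels, source = "crf") {
  purrr::map_dfr(seq_len(nrow(corpus)), function(i) {
    d <- corpus$doc_id[i]
    lab <- labels$label[labels$doc_id == d][order(labels$token_id[labels$doc_id == d])]
    bio_to_mentions(corpus$tokens[[i]], lab, d, corpus$text[i], source = source)
  })
}

#' Write tokens + labels as CoNLL-style delimited text
#'
#' One token per line (tab-separated), blank line between sentences, label
#' in the last column.  Columns are token text, optional feature columns,
#' then the label.  [read_conll()] inverts the export exactly (token text,
#' features, labels and sentence breaks; character offsets are not stored in
#' this interchange format).
#'
#' @param tokens Token tibble for one document.
#' @param labels Label vector, one per token.
#' @param features Optional data frame of extra columns (one row per token).
#' @param path Output file; when `NULL` the lines are returned invisibly.
#' @return Invisibly the written lines.
#' @export
write_conll <- function(tokens, labels, features = NULL, path = NULL) {
  stopifnot(length(labels) == nrow(tokens))
  cols <- cbind(text = tokens$text,
                if (!is.null(features)) as.data.frame(features, stringsAsFactors = FALSE),
                label = labels)
  body <- apply(cols, 1, paste, collapse = "\t")
  out <- character(0)
  for (s in unique(tokens$sent)) {
    out <- c(out, body[tokens$sent == s], "")
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' @rdname write_conll
#' @param lines Character vector of CoNLL lines (or a file path).
#' @return `read_conll()`: a tibble `text`, feature columns, `label`, `sent`.
#' @export
read_conll <- function(lines) {
  if (length(lines) == 1 && file.exists(lines)) lines <- readLines(lines, warn = FALSE)
  if (length(lines) && lines[length(lines)] == "") lines <- lines[-length(lines)]
  sent <- cumsum(c(1L, as.integer(lines[-length(lines)] == "")))
  keep <- lines != ""
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncol <- length(parts[[1]])
  df <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(df) <- c("text", if (ncol > 2) paste0("f", seq_len(ncol - 2)), "label")
  out <- tibble::as_tibble(df)
  out$sent <- match(sent[keep], unique(sent[keep]))
  out
}
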