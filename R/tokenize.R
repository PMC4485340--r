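# Tokenisation, sentence splitting and the POS/lemma provider.
#
# Offsets are 0-based, half-open throughout: a token spans [start, end) of
# the document string, so substr(text, start + 1, end) == token text.

# Closed-class words for the rule-based POS provider.
.pos_closed <- c(
  DT = "the|a|an|this|that|these|those|each|every|either|neither|some|any|no|all|both",
  IN = "of|in|on|at|by|for|with|from|to|into|onto|against|between|within|during|without|through|over|under|after|before|as|than|if|because|while|since|although|whether",
  CC = "and|or|but|nor|yet",
  PRP = "we|i|you|he|she|it|they|them|us|him|her",
  MD = "can|could|may|might|must|shall|should|will|would",
  VBD = "was|were|did|had|ran|used|performed|applied|obtained|compared|developed|implemented|provided|showed|allowed",
  VBZ = "is|has|does|provides|allows|contains|uses|runs|generates|shows|gives|offers|supports|requires|performs",
  VBP = "are|have|do|use|run|provide|allow|contain|generate|show|give|offer|support|require|perform",
  RB = "not|also|only|very|here|there|however|often|then|thus|frequently|typically|directly|dynamically|elsewhere"
)

.token_regex <- function(preserve_identifiers = TRUE) {
  pats <- c(
    "(?:https?://|www\\.)[^\\s]+[^\\s.,;:!?)]",       # URLs
    if (preserve_identifiers) "[A-Za-z]+:[0-9]+",      # database identifiers, e.g. GO:0007089
    "[vV][0-9]+(?:\\.[0-9]+)+",                        # version strings, e.g. v1.10
    "[0-9]+(?:\\.[0-9]+)+",                            # decimal numbers
    "[A-Za-z0-9]+",                                    # alphanumeric runs
    "[^A-Za-z0-9\\s]"                                  # any other visible character
  )
  paste0("(?:", paste(pats, collapse = "|"), ")")
}

.split_sentences <- function(text) {
  # Returns 0-based half-open [start, end) character spans of sentences.
  # A sentence ends at . ! or ? followed by whitespace; trailing text forms
  # the last sentence.  Decimals and identifiers never qualify because
  # their periods are not followed by whitespace.
  brk <- gregexpr("[.!?]+(?=\\s)", text, perl = TRUE)[[1]]
  ends <- if (brk[1] == -1L) integer(0) else as.integer(brk) + attr(brk, "match.length") - 1L
  starts0 <- c(0L, ends)
  ends0 <- c(ends, nchar(text))
  keep <- starts0 < ends0
  tibble::tibble(start = starts0[keep], end = ends0[keep])
}

.pos_tag <- function(token) {
  # Penn-style heuristic tagger.  Good enough to honour the provider
  # contract (deterministic, Penn vocabulary); not a linguistic parser.
  lower <- tolower(token)
  tag <- character(length(token))
  for (nm in names(.pos_closed)) {
    hit <- tag == "" & grepl(paste0("^(?:", .pos_closed[[nm]], ")$"), lower, perl = TRUE)
    tag[hit] <- nm
  }
  digits <- tag == "" & grepl("^[0-9]+(?:\\.[0-9]+)*$", token)
  tag[digits] <- "CD"
  punct <- tag == "" & grepl("^[^A-Za-z0-9]+$", token)
  tag[punct] <- token[punct]
  vbg <- tag == "" & grepl("^[a-z]+ing$", token) & nchar(token) > 4
  tag[vbg] <- "VBG"
  vbn <- tag == "" & grepl("^[a-z]+ed$", token) & nchar(token) > 3
  tag[vbn] <- "VBN"
  jj <- tag == "" & grepl("^[a-z]+(?:al|ous|ive|ble|ic)$", token) & nchar(token) > 4
  tag[jj] <- "JJ"
  nnp <- tag == "" & grepl("^[A-Z]", token)
  tag[nnp] <- "NNP"
  nns <- tag == "" & grepl("^[a-z]+s$", token) & nchar(token) > 3
  tag[nns] <- "NNS"
  tag[tag == ""] <- "NN"
  tag
}

#' Tokenise a document
#'
#' Splits text into sentences and character-offset tokens, attaching a
#' Penn-style POS tag and a lemma (lower-cased surface) to each token.
#' Offsets are 0-based and half-open, so
#' `substr(text, start + 1, end)` recovers the token surface.
#'
#' Tokens are maximal alphanumeric runs; every other non-whitespace
#' character is its own token.  Two extensions keep domain strings intact:
#' decimal/version numbers (`1.83`) and, when `preserve_identifiers = TRUE`
#' (the default), database identifiers of the form letters + `:` + digits
#' (`GO:0007089`) stay single tokens.  Keeping identifiers whole stops
#' dictionary names such as `GO` from matching inside record identifiers, a
#' known false-positive source for this task.
#'
#' @param text Document text (non-empty string).
#' @param preserve_identifiers Keep `XX:digits` identifiers as one token.
#' @return A tibble with one row per token: `token_id` (1-based), `text`,
#'   `start`, `end` (0-based half-open character offsets), `pos`, `lemma`
#'   and `sent` (1-based sentence index).
#' @examples
#' tokenize_text("BLAST was run.")
#' tokenize_text("GO:0007089", preserve_identifiers = FALSE)
#' @export
tokenize_text <- function(text, preserve_identifiers = TRUE) {
  stopifnot(is.character(text), length(text) == 1)
  if (is.na(text) || !nzchar(text)) {
    stop("cannot tokenise empty text: document has no content", call. = FALSE)
  }
  sents <- .split_sentences(text)
  rx <- .token_regex(preserve_identifiers)
  out <- vector("list", nrow(sents))
  for (si in seq_len(nrow(sents))) {
    seg <- substr(text, sents$start[si] + 1L, sents$end[si])
    m <- gregexpr(rx, seg, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    st <- sents$start[si] + as.integer(m) - 1L
    en <- st + attr(m, "match.length")
    out[[si]] <- tibble::tibble(
      text = substring(text, st + 1L, en),
      start = st, end = en, sent = si
    )
  }
  toks <- dplyr::bind_rows(out)
  if (nrow(toks) == 0) {
    return(tibble::tibble(
      token_id = integer(), text = character(), start = integer(),
      end = integer(), pos = character(), lemma = character(), sent = integer()
    ))
  }
  toks$sent <- match(toks$sent, unique(toks$sent))
  tibble::tibble(
    token_id = seq_len(nrow(toks)),
    text = toks$text,
    start = toks$start,
    end = toks$end,
    pos = .pos_tag(toks$text),
    lemma = tolower(toks$text),
    sent = toks$sent
  )
}

#' Assemble a corpus tibble from raw documents
#'
#' @param docs A data frame with columns `doc_id`, `text` and optionally
#'   `title` (used by the title-pattern clue detector).
#' @param preserve_identifiers Passed to [tokenize_text()].
#' @return A corpus tibble: `doc_id`, `title`, `text` and a `tokens`
#'   list-column of per-document token tibbles.
#' @examples
#' as_corpus(tibble::tibble(doc_id = "d1", text = "We ran BLAST."))
#' @export
as_corpus <- function(docs, preserve_identifiers = TRUE) {
  stopifnot(is.data.frame(docs), all(c("doc_id", "text") %in% names(docs)))
  if (anyDuplicated(docs$doc_id)) stop("duplicate doc_id in corpus", call. = FALSE)
  tibble::tibble(
    doc_id = as.character(docs$doc_id),
    title = if ("title" %in% names(docs)) as.character(docs$title) else "",
    text = as.character(docs$text),
    tokens = purrr::map(docs$text, tokenize_text,
                        preserve_identifiers = preserve_identifiers)
  )
}

#' Check token invariants for one document
#'
#' Verifies offsets are in range, token surfaces slice out of the text, and
#' tokens are sorted and non-overlapping.  Called by readers and the
#' synthetic generator; errors name the first violation.
#'
#' @param tokens Token tibble as returned by [tokenize_text()].
#' @param text The document text the tokens index into.
#' @return Invisibly `TRUE`; errors on violation.
#' @export
validate_tokens <- function(tokens, text) {
  if (nrow(tokens) == 0) return(invisible(TRUE))
  n <- nchar(text)
  bad <- which(!(tokens$start >= 0 & tokens$start < tokens$end & tokens$end <= n))
  if (length(bad)) {
    stop(sprintf("token %d has offsets [%d,%d) outside text of length %d",
                 bad[1], tokens$start[bad[1]], tokens$end[bad[1]], n), call. = FALSE)
  }
  sl <- substring(text, tokens$start + 1L, tokens$end)
  bad <- which(sl != tokens$text)
  if (length(bad)) {
    stop(sprintf("token %d surface %s does not match text slice %s",
                 bad[1], dQuote(tokens$text[bad[1]]), dQuote(sl[bad[1]])), call. = FALSE)
  }
  if (nrow(tokens) > 1 && any(tokens$start[-1] < tokens$end[-nrow(tokens)])) {
    stop("tokens overlap or are unsorted", call. = FALSE)
  }
  invisible(TRUE)
}
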