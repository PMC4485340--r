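# Shared fixture builders.  Everything is generated in code; no binary
# fixtures.

# A tiny corpus from raw texts (named vector: doc_id -> text).
toy_corpus <- function(texts, titles = NULL) {
  as_corpus(tibble::tibble(
    doc_id = names(texts), text = unname(texts),
    title = if (is.null(titles)) "" else unname(titles)))
}

# A dictionary from a named list canonical -> c(rtype, pipe-variants).
toy_dict <- function(...) {
  rows <- list(...)
  new_dictionary(tibble::tibble(
    canonical = purrr::map_chr(rows, 1),
    rtype = purrr::map_chr(rows, 2),
    source = "test",
    variants = purrr::map_chr(rows, ~ if (length(.x) >= 3) .x[[3]] else "")
  ))
}

# Random non-overlapping token-aligned mentions for a document.
random_mentions <- function(tokens, text, doc_id, n = 3L) {
  if (nrow(tokens) == 0 || n == 0) return(resner:::.mention_cols())
  picks <- sort(sample(nrow(tokens), min(n, nrow(tokens))))
  # drop adjacent picks to keep mentions separated, then random lengths
  picks <- picks[c(TRUE, diff(picks) > 2)]
  purrr::map_dfr(picks, function(i) {
    j <- min(nrow(tokens), i + sample(0:1, 1))
    if (tokens$sent[j] != tokens$sent[i]) j <- i
    new_mentions(doc_id, tokens$start[i], tokens$end[j],
                 substr(text, tokens$start[i] + 1, tokens$end[j]))
  })
}

# Default small synthetic world shared by several tests.
synth_world <- function(n_docs = 12, seed = 11, ...) {
  dict <- make_toy_dictionary(25, seed = seed)
  g <- generate_corpus(synth_config(n_docs = n_docs, seed = seed, ...), dict)
  g
}
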