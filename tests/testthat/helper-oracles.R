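# Independent brute-force oracles used by both the module tests and the
# acceptance suite.  They re-state the definitions literally and stay
# independent of the implementation paths they check.

# Enumerate every token n-gram / variant equality (same case policy and
# identifier suppression as documented), then leftmost-longest selection.
brute_match <- function(tokens, dict, text) {
  spans <- list()
  for (i in seq_len(nrow(tokens))) {
    for (j in i:min(nrow(tokens), i + 9)) {
      if (tokens$sent[j] != tokens$sent[i]) break
      surface <- substr(text, tokens$start[i] + 1, tokens$end[j])
      ns <- gsub("\\s+", " ", trimws(surface))
      for (v in unique(dict$variants$variant)) {
        strict <- nchar(v) <= 4 || v == toupper(v)
        hit <- if (strict) ns == v else tolower(ns) == tolower(v)
        if (hit && !grepl("^:[0-9]",
                          substr(text, tokens$end[j] + 1, tokens$end[j] + 2))) {
          spans[[length(spans) + 1]] <- c(tokens$start[i], tokens$end[j])
        }
      }
    }
  }
  if (!length(spans)) return(matrix(numeric(), ncol = 2))
  spans <- unique(do.call(rbind, spans))
  spans <- spans[order(spans[, 1], -spans[, 2]), , drop = FALSE]
  sel <- matrix(numeric(), ncol = 2)
  pos <- -1
  for (r in seq_len(nrow(spans))) {
    if (spans[r, 1] >= pos) {
      sel <- rbind(sel, spans[r, ])
      pos <- spans[r, 2]
    }
  }
  sel
}

# Literal re-implementation of the second pass: walk every token and
# re-check all three promotion conditions from their definitions.
brute_second_pass <- function(corpus, labels, dict, blacklist) {
  surf_all <- purrr::map_dfr(seq_len(nrow(corpus)), function(i) {
    tibble::tibble(doc_id = corpus$doc_id[i],
                   token_id = corpus$tokens[[i]]$token_id,
                   surface = corpus$tokens[[i]]$text)
  })
  j <- dplyr::inner_join(surf_all, labels, by = c("doc_id", "token_id"))
  out <- j
  for (r in seq_len(nrow(out))) {
    if (out$label[r] != "O") next
    s <- out$surface[r]
    lab_n <- sum(j$surface == s & j$label != "O")
    unlab_n <- sum(j$surface == s & j$label == "O")
    cond1 <- lab_n > unlab_n
    cond2 <- dict_flag(s, dict) || grepl("^[A-Z]{2,}$", s)
    cond3 <- !tolower(s) %in% tolower(blacklist)
    if (cond1 && cond2 && cond3) out$label[r] <- "P"
  }
  for (d in unique(out$doc_id)) {
    idx <- which(out$doc_id == d)
    toks <- corpus$tokens[[match(d, corpus$doc_id)]]
    prev_p <- FALSE
    for (k in seq_along(idx)) {
      if (out$label[idx[k]] == "P") {
        same_sent <- k > 1 && toks$sent[k] == toks$sent[k - 1]
        out$label[idx[k]] <- if (prev_p && same_sent) "I" else "B"
        prev_p <- TRUE
      } else prev_p <- FALSE
    }
  }
  out$label
}
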