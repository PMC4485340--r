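# Two-pass post-processing.  The first tagging pass often recognises a
# resource name once in a document and misses its repetitions; the second
# pass harvests corpus-wide votes for each token surface and promotes
# repeatedly-tagged-but-missed tokens under strict eligibility conditions.

#' Default token blacklist for second-pass promotion
#'
#' Four common words that caused a large share of false positives when
#' promoted; they are never labelled in the second pass.  Comparison is
#' case-insensitive.
#' @export
DEFAULT_BLACKLIST <- c("analysis", "genomes", "cycle", "cell")

#' Collect corpus-wide tagging votes per token surface
#'
#' For every exact (case-sensitive) token surface in the tagged corpus,
#' counts how often pass-1 labelled it as part of a resource name (`B` or
#' `I`) versus `O`.  Votes come from the corpus currently being tagged
#' (transductive), not from training data.
#'
#' @param corpus Corpus tibble.
#' @param labels Flat label tibble (pass-1 output).
#' @return A tibble `surface`, `labelled`, `unlabelled` covering every
#'   token surface in the corpus.
#' @export
collect_token_votes <- function(corpus, labels) {
  toks <- purrr::map_dfr(seq_len(nrow(corpus)), function(i) {
    tibble::tibble(doc_id = corpus$doc_id[i],
                   token_id = corpus$tokens[[i]]$token_id,
                   surface = corpus$tokens[[i]]$text)
  })
  joined <- dplyr::inner_join(toks, labels, by = c("doc_id", "token_id"))
  if (nrow(joined) != nrow(toks)) {
    stop("labels do not cover every token of the corpus", call. = FALSE)
  }
  joined |>
    dplyr::group_by(.data$surface) |>
    dplyr::summarise(labelled = sum(.data$label != "O"),
                     unlabelled = sum(.data$label == "O"),
                     .groups = "drop")
}

#' Acronym eligibility for second-pass promotion
#'
#' `TRUE` iff the token is all capital letters, contains no digits, and is
#' at least two characters long.  Deliberately stricter than the
#' orthographic `isAcronym` feature, which admits digits.
#'
#' @param token Character vector.
#' @return Logical vector.
#' @examples
#' acronym_eligible(c("AB", "A1", "A"))  # TRUE FALSE FALSE
#' @export
acronym_eligible <- function(token) {
  grepl("^[A-Z]{2,}$", token)
}

#' Second-pass relabelling
#'
#' Promotes a pass-1 `O` token to part of a mention iff all three
#' conditions hold:
#' 1. across the corpus being tagged, its exact surface was labelled more
#'    often than not (strict majority; ties reject);
#' 2. it is in the resource dictionary ([dict_flag()]) or is an eligible
#'    acronym ([acronym_eligible()]);
#' 3. its surface is not blacklisted (case-insensitive).
#'
#' Existing `B`/`I` labels are never removed, so token-level recall cannot
#' decrease.  Contiguous promoted tokens merge into one mention: the first
#' gets `B`, the rest `I`.
#'
#' @param corpus Corpus tibble.
#' @param labels Pass-1 flat label tibble.
#' @param votes Vote tibble from [collect_token_votes()] over this corpus.
#' @param dict A `resource_dictionary` (may be empty).
#' @param blacklist Character vector of never-promoted word forms.
#' @return A flat label tibble with promotions applied.
#' @export
second_pass_relabel <- function(corpus, labels, votes, dict,
                                blacklist = DEFAULT_BLACKLIST) {
  promote_surface <- votes$surface[votes$labelled > votes$unlabelled]
  eligible <- promote_surface[
    (if (is.null(dict)) FALSE else dict_flag(promote_surface, dict)) |
      acronym_eligible(promote_surface)]
  eligible <- eligible[!tolower(eligible) %in% tolower(blacklist)]
  purrr::map_dfr(seq_len(nrow(corpus)), function(i) {
    d <- corpus$doc_id[i]
    toks <- corpus$tokens[[i]]
    sel <- labels$doc_id == d
    if (!any(sel)) {
      stop("labels missing for document ", d, " (votes/corpus mismatch?)",
           call. = FALSE)
    }
    lab <- labels$label[sel][order(labels$token_id[sel])]
    if (length(lab) != nrow(toks)) {
      stop("label sequence length mismatch for document ", d, call. = FALSE)
    }
    promo <- lab == "O" & toks$text %in% eligible
    if (any(promo)) {
      run_start <- promo & !c(FALSE, promo[-length(promo)] &
                                toks$sent[-length(promo)] == toks$sent[-1])
      lab[promo] <- "I"
      lab[promo & run_start] <- "B"
    }
    tibble::tibble(doc_id = d, token_id = toks$token_id,
                   label = repair_bio(lab, toks$sent))
  })
}

#' One-call post-processing
#'
#' Convenience wrapper: collect votes from the pass-1 labels and apply
#' [second_pass_relabel()].
#'
#' @inheritParams second_pass_relabel
#' @return Relabelled flat label tibble.
#' @export
postprocess_labels <- function(corpus, labels, dict,
                               blacklist = DEFAULT_BLACKLIST) {
  votes <- collect_token_votes(corpus, labels)
  second_pass_relabel(corpus, labels, votes, dict, blacklist = blacklist)
}
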