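# Descriptive analytics of annotated corpora and of resource names:
# corpus summary statistics, stemmed token frequencies, POS-pattern
# profiles and name variability.

#' Corpus summary statistics
#'
#' Aggregates gold mentions over a corpus: totals, unique surface strings
#' (distinct exact, case-sensitive surfaces — "lexically unique" names),
#' per-document means, single-document maxima, singleton surfaces (those
#' mentioned exactly once in the corpus) and the fraction of mentions typed
#' as databases.
#'
#' @param corpus Corpus tibble.
#' @param mentions Gold mention tibble.
#' @return A one-row tibble: `n_docs`, `total_mentions`,
#'   `unique_surface_mentions`, `mean_mentions_per_doc`,
#'   `mean_unique_per_doc`, `max_mentions_single_doc`,
#'   `max_unique_single_doc`, `singleton_surface_count`,
#'   `db_mention_fraction`.
#' @export
corpus_summary <- function(corpus, mentions) {
  if (nrow(corpus) == 0) stop("empty corpus", call. = FALSE)
  per_doc <- purrr::map_dfr(corpus$doc_id, function(d) {
    m <- mentions[mentions$doc_id == d, ]
    tibble::tibble(doc_id = d, n = nrow(m), n_unique = length(unique(m$surface)))
  })
  counts <- table(mentions$surface)
  tibble::tibble(
    n_docs = nrow(corpus),
    total_mentions = nrow(mentions),
    unique_surface_mentions = length(counts),
    mean_mentions_per_doc = nrow(mentions) / nrow(corpus),
    mean_unique_per_doc = mean(per_doc$n_unique),
    max_mentions_single_doc = max(per_doc$n),
    max_unique_single_doc = max(per_doc$n_unique),
    singleton_surface_count = sum(counts == 1),
    db_mention_fraction = if (nrow(mentions))
      mean(mentions$rtype == "DATABASE") else NA_real_
  )
}

#' Stemmed token frequencies within names
#'
#' Whitespace-tokenises each name, Porter-stems each token and counts stem
#' occurrences, ranking descending with an alphabetical tie-break.  Profiles
#' the lexical composition of resource names (head words like "database"
#' dominate dictionaries of biomedical resources).
#'
#' @param names Character vector of names (empty strings are skipped with a
#'   warning), or a `resource_dictionary` (all variants are used).
#' @return A tibble `stem`, `count`, ranked.
#' @examples
#' stem_token_frequency(c("Gene Ontology", "Gene Database"))
#' @export
stem_token_frequency <- function(names) {
  if (inherits(names, "resource_dictionary")) names <- names$variants$variant
  blank <- !nzchar(trimws(names))
  if (any(blank)) {
    warning(sum(blank), " empty name(s) skipped")
    names <- names[!blank]
  }
  if (!length(names)) return(tibble::tibble(stem = character(), count = integer()))
  toks <- unlist(strsplit(names, "\\s+"), use.names = FALSE)
  toks <- toks[nzchar(toks)]
  stems <- porter_stem(toks)
  tab <- table(stems)
  tibble::tibble(stem = names(tab), count = as.integer(tab)) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$stem)
}

#' POS-pattern profile of mention structure
#'
#' The pattern of a mention is the space-joined sequence of POS tags over
#' its tokens.  Patterns are counted over unique (surface, pattern) pairs,
#' so a surface tagged differently in two places contributes two patterns.
#' Percentages are of the total pattern count.
#'
#' @param corpus Corpus tibble (token POS tags are taken from it), or
#'   `NULL` when `patterns` is supplied directly.
#' @param mentions Gold mention tibble.
#' @param patterns Optional pre-computed tibble `surface`, `pattern`
#'   (bypasses the corpus lookup; used when patterns come from an external
#'   tagger).
#' @return A tibble `pattern`, `count`, `percentage`, ranked descending
#'   with alphabetical tie-break.
#' @export
pos_pattern_profile <- function(corpus, mentions, patterns = NULL) {
  if (is.null(patterns)) {
    patterns <- purrr::map_dfr(seq_len(nrow(mentions)), function(i) {
      d <- mentions$doc_id[i]
      toks <- corpus$tokens[[match(d, corpus$doc_id)]]
      idx <- which(toks$end > mentions$start[i] & toks$start < mentions$end[i])
      tibble::tibble(surface = mentions$surface[i],
                     pattern = paste(toks$pos[idx], collapse = " "))
    })
  }
  uniq <- dplyr::distinct(patterns, .data$surface, .data$pattern)
  tab <- uniq |>
    dplyr::count(.data$pattern, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$pattern)
  tab$percentage <- 100 * tab$count / sum(tab$count)
  tab
}

#' Name variability: variants per resource
#'
#' The dictionary-level variability is the number of unique variants
#' (after whitespace normalisation) divided by the number of resources.
#' For corpus names, supply a grouping (`resource`, `variant`) built from
#' domain knowledge — grouping surface forms into resources is editorial,
#' not algorithmic.
#'
#' @param x A `resource_dictionary`, or a data frame with columns
#'   `resource` and `variant`, or `NULL` when raw counts are given.
#' @param n_variants,n_resources Raw counts, used when `x` is `NULL` (for
#'   recomputing published aggregates).
#' @return A list with `mean` (variants per resource), `n_variants`,
#'   `n_resources` and `distribution` (tibble `n_variants_per_resource`,
#'   `n_resources`; empty when only raw counts are given).
#' @examples
#' variability_stats(n_variants = 6929, n_resources = 6126)$mean  # 1.13
#' @export
variability_stats <- function(x = NULL, n_variants = NULL, n_resources = NULL) {
  if (is.null(x)) {
    stopifnot(!is.null(n_variants), !is.null(n_resources))
    if (n_resources == 0) stop("zero resources", call. = FALSE)
    return(list(mean = n_variants / n_resources,
                n_variants = n_variants, n_resources = n_resources,
                distribution = tibble::tibble(n_variants_per_resource = integer(),
                                              n_resources = integer())))
  }
  groups <- if (inherits(x, "resource_dictionary")) {
    tibble::tibble(resource = x$variants$entry_id, variant = x$variants$variant)
  } else {
    stopifnot(all(c("resource", "variant") %in% names(x)))
    tibble::as_tibble(x[, c("resource", "variant")])
  }
  if (!nrow(groups)) stop("zero resources", call. = FALSE)
  groups$variant <- .norm_ws(groups$variant)
  per <- groups |>
    dplyr::distinct(.data$resource, .data$variant) |>
    dplyr::count(.data$resource, name = "nv")
  total_unique <- length(unique(groups$variant))
  dist <- per |>
    dplyr::count(.data$nv, name = "n_resources") |>
    dplyr::rename(n_variants_per_resource = "nv")
  list(mean = total_unique / nrow(per),
       n_variants = total_unique, n_resources = nrow(per),
       distribution = dist)
}
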