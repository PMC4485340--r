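# Token-level features for sequence labelling: shape, orthographic,
# lexical, dictionary and syntactic groups, assembled over a fixed
# context window (default two tokens back, one forward).

#' Token shape features
#'
#' `token_shape()` maps every character to its class: capital letter to
#' `X`, lower-case letter to `x`, digit to `d`, anything else to `S`
#' (`"MySQL"` becomes `"XxXXX"`).  `shape_signature()` compresses a token
#' to a fixed four-character presence string in the order capital, lower,
#' digit, other, with `_` marking absence (`"MySQL"` becomes `"Xx__"`).
#'
#' @param token Character vector of non-empty tokens.
#' @return Character vector, same length as `token`.
#' @examples
#' token_shape("MySQL")      # "XxXXX"
#' shape_signature("MySQL")  # "Xx__"
#' @export
token_shape <- function(token) {
  if (any(!nzchar(token) | is.na(token))) {
    stop("token shape is undefined for empty tokens", call. = FALSE)
  }
  out <- gsub("[A-Z]", "X", token)
  out <- gsub("[a-z]", "x", out)
  out <- gsub("[0-9]", "d", out)
  gsub("[^Xxd]", "S", out)
}

#' @rdname token_shape
#' @export
shape_signature <- function(token) {
  if (any(!nzchar(token) | is.na(token))) {
    stop("shape signature is undefined for empty tokens", call. = FALSE)
  }
  paste0(ifelse(grepl("[A-Z]", token), "X", "_"),
         ifelse(grepl("[a-z]", token), "x", "_"),
         ifelse(grepl("[0-9]", token), "d", "_"),
         ifelse(grepl("[^A-Za-z0-9]", token), "S", "_"))
}

#' Orthographic flags
#'
#' Six boolean features per token, each defined by a regular expression:
#' * `isAcronym` — two or more characters, starts with a capital, all
#'   capitals or digits, at least two letters (`"SCOP"` yes, `"S4"` no);
#' * `containsAllCaps` — every letter is a capital (and there is one);
#' * `isCapitalised` — the first letter in the token is a capital;
#' * `containsCapLetter` — at least one capital letter;
#' * `containsDigits` — at least one digit;
#' * `isAllDigits` — digits only.
#'
#' By construction `containsAllCaps` implies `isCapitalised` implies
#' `containsCapLetter`, and `isAllDigits` implies `containsDigits`.
#'
#' @param token Character vector.
#' @return A tibble of six logical columns.
#' @examples
#' ortho_flags(c("SCOP", "UniProt", "2016"))
#' @export
ortho_flags <- function(token) {
  tibble::tibble(
    isAcronym = grepl("^(?=(?:[0-9]*[A-Z]){2})[A-Z][A-Z0-9]+$", token, perl = TRUE),
    containsAllCaps = grepl("^[^a-z]*[A-Z][^a-z]*$", token),
    isCapitalised = grepl("^[^A-Za-z]*[A-Z]", token),
    containsCapLetter = grepl("[A-Z]", token),
    containsDigits = grepl("[0-9]", token),
    isAllDigits = grepl("^[0-9]+$", token)
  )
}

#' Dictionary membership flag
#'
#' `TRUE` when the token equals a dictionary variant or equals one of the
#' whitespace-delimited tokens of a multi-word variant.  The comparison
#' follows the matcher's case policy: short or all-caps words compare
#' case-sensitively, longer mixed-case words also case-insensitively.
#'
#' @param token Character vector.
#' @param dict A `resource_dictionary`.
#' @return Logical vector.
#' @export
dict_flag <- function(token, dict) {
  words <- unique(unlist(strsplit(dict$variants$variant, "\\s+"), use.names = FALSE))
  words <- words[nzchar(words)]
  if (!length(words)) return(rep(FALSE, length(token)))
  cs <- .case_sensitive_variant(words)
  exact <- token %in% words
  loose <- tolower(token) %in% tolower(words[!cs])
  exact | loose
}

#' Concatenated syntactic-relation feature
#'
#' Sorts the dependency relation labels a token participates in and joins
#' them with underscores (`{pobj, advmod}` becomes `"advmod_pobj"`); tokens
#' with no relations get the sentinel `"NONE"`.  Relations come from an
#' optional provider; the package ships none, so the sentinel is the
#' default everywhere unless a `relations` column is supplied.
#'
#' @param relations A list of character vectors (one per token) or a single
#'   character vector for one token.
#' @return Character vector of combined relation strings.
#' @examples
#' syntactic_feature(list(c("pobj", "advmod"), "nsubj", character()))
#' @export
syntactic_feature <- function(relations) {
  if (!is.list(relations)) relations <- list(relations)
  purrr::map_chr(relations, function(r) {
    r <- r[nzchar(r)]
    if (!length(r)) "NONE" else paste(sort(unique(tolower(r))), collapse = "_")
  })
}

#' Feature configuration
#'
#' @param window Integer offsets of neighbour tokens whose features are
#'   copied into the current token's vector.  The default `c(-2, -1, 1)` —
#'   two tokens before and one after — is the window that performed best in
#'   development for this task.
#' @param groups Feature groups to include: any of `"lexical"`,
#'   `"orthographic"`, `"dictionary"`, `"syntactic"`.
#' @return A `feature_config` list.
#' @export
feature_config <- function(window = c(-2L, -1L, 1L),
                           groups = c("lexical", "orthographic", "dictionary", "syntactic")) {
  bad <- setdiff(groups, c("lexical", "orthographic", "dictionary", "syntactic"))
  if (length(bad)) stop("unknown feature group: ", bad[1], call. = FALSE)
  structure(list(window = as.integer(window), groups = groups),
            class = "feature_config")
}

# Per-token base features as a data frame of character columns.
.base_features <- function(tokens, dict, config, relations = NULL) {
  out <- tibble::tibble(.rows = nrow(tokens))
  if ("lexical" %in% config$groups) {
    out$word <- tokens$text
    out$lemma <- tokens$lemma
    out$pos <- tokens$pos
  }
  if ("orthographic" %in% config$groups) {
    out$shape <- token_shape(tokens$text)
    out$sig <- shape_signature(tokens$text)
    fl <- ortho_flags(tokens$text)
    for (nm in names(fl)) out[[nm]] <- ifelse(fl[[nm]], "1", "0")
  }
  if ("dictionary" %in% config$groups) {
    out$inDict <- if (is.null(dict)) "0" else ifelse(dict_flag(tokens$text, dict), "1", "0")
  }
  if ("syntactic" %in% config$groups) {
    out$dep <- if (is.null(relations)) rep("NONE", nrow(tokens))
               else syntactic_feature(relations)
  }
  out
}

#' Windowed feature vectors for a document
#'
#' Builds the full per-token feature table: the token's own feature groups
#' plus copies of each neighbour's features at the configured offsets.
#' Offsets that fall outside the sentence are filled with the boundary
#' sentinels `__BOS__` / `__EOS__`, so the feature space is identical at
#' sentence edges.  Extraction is pure: identical tokens in identical
#' contexts always produce identical rows.
#'
#' @param tokens Token tibble for one document.
#' @param dict Optional `resource_dictionary` for the dictionary group.
#' @param config A [feature_config()].
#' @param relations Optional list of per-token dependency relation labels.
#' @return A tibble with one row per token; neighbour columns are named
#'   `w[offset].feature`.
#' @export
token_features <- function(tokens, dict = NULL, config = feature_config(),
                           relations = NULL) {
  base <- .base_features(tokens, dict, config, relations)
  if (!nrow(base)) return(base)
  out <- base
  n <- nrow(tokens)
  idx <- seq_len(n)
  for (off in config$window) {
    nb <- idx + off
    ok <- nb >= 1 & nb <= n
    ok[ok] <- tokens$sent[nb[ok]] == tokens$sent[idx[ok]]
    sentinel <- if (off < 0) "__BOS__" else "__EOS__"
    for (nm in names(base)) {
      col <- rep(sentinel, n)
      col[ok] <- base[[nm]][nb[ok]]
      out[[sprintf("w[%d].%s", off, nm)]] <- col
    }
  }
  out
}

# Feature table -> list of "name=value" string vectors, the learner's and
# the CoNLL exporter's shared representation.
.feature_strings <- function(feat) {
  if (!nrow(feat)) return(list())
  nms <- names(feat)
  mat <- as.matrix(feat)
  purrr::map(seq_len(nrow(mat)), function(i) paste0(nms, "=", mat[i, ]))
}
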