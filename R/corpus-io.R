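# Standoff annotation I/O (brat-style .txt/.ann pairs) and JSON-lines
# interchange.  Mentions are flat tibbles keyed by doc_id with 0-based
# half-open character offsets.

.mention_cols <- function() {
  tibble::tibble(
    doc_id = character(), start = integer(), end = integer(),
    surface = character(), rtype = character(), source = character()
  )
}

#' Construct a mention tibble
#'
#' @param doc_id,start,end,surface,rtype,source Vectors recycled to a common
#'   length.  `rtype` is one of `DATABASE`, `SOFTWARE`, `UNSPECIFIED`;
#'   `source` one of `gold`, `dictionary`, `crf`, `postprocess`, `clue`.
#' @return A mention tibble sorted by `doc_id` then `start`.
#' @export
new_mentions <- function(doc_id = character(), start = integer(), end = integer(),
                         surface = character(), rtype = "UNSPECIFIED", source = "gold") {
  out <- tibble::tibble(
    doc_id = as.character(doc_id), start = as.integer(start),
    end = as.integer(end), surface = as.character(surface),
    rtype = rtype, source = source
  )
  dplyr::arrange(out, .data$doc_id, .data$start)
}

#' Validate mentions against a corpus
#'
#' Checks offsets are in range, surfaces equal the text slice and mentions
#' within a document do not overlap.
#'
#' @param mentions Mention tibble.
#' @param corpus Corpus tibble from [as_corpus()].
#' @return Invisibly `TRUE`; errors name the offending document and offset.
#' @export
validate_mentions <- function(mentions, corpus) {
  if (nrow(mentions) == 0) return(invisible(TRUE))
  txt <- stats::setNames(corpus$text, corpus$doc_id)
  missing <- setdiff(unique(mentions$doc_id), names(txt))
  if (length(missing)) {
    stop("mentions reference unknown document: ", missing[1], call. = FALSE)
  }
  for (d in unique(mentions$doc_id)) {
    m <- dplyr::arrange(mentions[mentions$doc_id == d, ], .data$start)
    n <- nchar(txt[[d]])
    bad <- which(!(m$start >= 0 & m$start < m$end & m$end <= n))
    if (length(bad)) {
      stop(sprintf("document %s: mention offsets [%d,%d) outside text length %d",
                   d, m$start[bad[1]], m$end[bad[1]], n), call. = FALSE)
    }
    sl <- substring(txt[[d]], m$start + 1L, m$end)
    bad <- which(sl != m$surface)
    if (length(bad)) {
      stop(sprintf("document %s: mention surface %s != text slice %s at offset %d",
                   d, dQuote(m$surface[bad[1]]), dQuote(sl[bad[1]]), m$start[bad[1]]),
           call. = FALSE)
    }
    if (nrow(m) > 1 && any(m$start[-1] < m$end[-nrow(m)])) {
      i <- which(m$start[-1] < m$end[-nrow(m)])[1]
      stop(sprintf("document %s: overlapping mentions at offsets %d and %d",
                   d, m$start[i], m$start[i + 1]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Read a brat-style standoff corpus
#'
#' Loads paired `<id>.txt` / `<id>.ann` files.  Annotation lines follow the
#' brat text-bound form `T1<TAB>Type start end<TAB>surface`; `Database` and
#' `Software` types map to mention `rtype`, anything else to `UNSPECIFIED`.
#' An optional first line `#title<TAB>...` in the .txt is treated as the
#' document title (offsets then index the remainder).  All mention
#' invariants are verified on load.
#'
#' @param dir Directory containing the file pairs.
#' @param preserve_identifiers Passed to [tokenize_text()].
#' @return A list with elements `corpus` (tibble) and `mentions` (tibble,
#'   `source = "gold"`).
#' @export
read_brat <- function(dir, preserve_identifiers = TRUE) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  if (!length(txts)) stop("no .txt files found in ", dir, call. = FALSE)
  docs <- vector("list", length(txts))
  anns <- vector("list", length(txts))
  for (i in seq_along(txts)) {
    doc_id <- sub("\\.txt$", "", basename(txts[i]))
    raw <- readChar(txts[i], file.size(txts[i]), useBytes = FALSE)
    raw <- gsub("\r\n", "\n", raw, fixed = TRUE)
    title <- ""
    if (startsWith(raw, "#title\t")) {
      nl <- regexpr("\n", raw, fixed = TRUE)
      title <- substr(raw, 8, nl - 1L)
      raw <- substr(raw, nl + 1L, nchar(raw))
    }
    docs[[i]] <- tibble::tibble(doc_id = doc_id, title = title, text = raw)
    ann_path <- file.path(dir, paste0(doc_id, ".ann"))
    if (file.exists(ann_path)) {
      lines <- readLines(ann_path, warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      if (length(lines)) {
        parts <- strsplit(lines, "\t", fixed = TRUE)
        rows <- purrr::imap(parts, function(p, j) {
          if (length(p) < 2 || !grepl("^T", p[[1]])) {
            stop(sprintf("%s line %d: not a text-bound annotation", ann_path, j),
                 call. = FALSE)
          }
          f <- strsplit(p[[2]], " ", fixed = TRUE)[[1]]
          if (length(f) != 3) {
            stop(sprintf("%s line %d: expected 'Type start end'", ann_path, j),
                 call. = FALSE)
          }
          tibble::tibble(
            doc_id = doc_id,
            start = as.integer(f[2]), end = as.integer(f[3]),
            surface = if (length(p) >= 3) p[[3]] else "",
            rtype = switch(toupper(f[1]),
                           DATABASE = "DATABASE", SOFTWARE = "SOFTWARE",
                           "UNSPECIFIED"),
            source = "gold"
          )
        })
        anns[[i]] <- dplyr::bind_rows(rows)
      }
    }
  }
  corpus <- as_corpus(dplyr::bind_rows(docs), preserve_identifiers)
  mentions <- dplyr::bind_rows(.mention_cols(), dplyr::bind_rows(anns))
  # fill surfaces omitted in the .ann and verify everything
  if (nrow(mentions)) {
    txt <- stats::setNames(corpus$text, corpus$doc_id)
    blank <- !nzchar(mentions$surface)
    mentions$surface[blank] <- substring(
      txt[mentions$doc_id[blank]], mentions$start[blank] + 1L, mentions$end[blank])
    validate_mentions(mentions, corpus)
    mentions <- dplyr::arrange(mentions, .data$doc_id, .data$start)
  }
  list(corpus = corpus, mentions = mentions)
}

#' Write a corpus as brat-style standoff files
#'
#' Inverse of [read_brat()]: one `<doc_id>.txt` (with a `#title` first line
#' when the document has a title) and one `<doc_id>.ann` per document.
#'
#' @param corpus Corpus tibble.
#' @param mentions Mention tibble.
#' @param dir Output directory (created if needed).
#' @return Invisibly `dir`.
#' @export
write_brat <- function(corpus, mentions, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(corpus))) {
    d <- corpus$doc_id[i]
    head <- if (nzchar(corpus$title[i])) paste0("#title\t", corpus$title[i], "\n") else ""
    writeChar(paste0(head, corpus$text[i]), file.path(dir, paste0(d, ".txt")),
              eos = NULL)
    m <- mentions[mentions$doc_id == d, , drop = FALSE]
    lines <- if (nrow(m)) {
      ty <- dplyr::case_match(m$rtype, "DATABASE" ~ "Database",
                              "SOFTWARE" ~ "Software", .default = "Resource")
      sprintf("T%d\t%s %d %d\t%s", seq_len(nrow(m)), ty, m$start, m$end, m$surface)
    } else character()
    writeLines(lines, file.path(dir, paste0(d, ".ann")))
  }
  invisible(dir)
}

#' Read / write JSON-lines document interchange
#'
#' One JSON object per line with fields `doc_id`, `title`, `text` and
#' `mentions` (array of `{start, end, surface, rtype, source}`).
#'
#' @param path File path.
#' @param preserve_identifiers Passed to [tokenize_text()].
#' @return `read_jsonl()`: a list with `corpus` and `mentions`;
#'   `write_jsonl()`: invisibly `path`.
#' @export
read_jsonl <- function(path, preserve_identifiers = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  objs <- purrr::map(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  docs <- purrr::map_dfr(objs, function(o) {
    tibble::tibble(doc_id = o$doc_id, title = o$title %||% "", text = o$text)
  })
  mentions <- purrr::map_dfr(objs, function(o) {
    m <- o$mentions
    if (is.null(m) || NROW(m) == 0) return(.mention_cols())
    tibble::tibble(doc_id = o$doc_id, start = as.integer(m$start),
                   end = as.integer(m$end), surface = m$surface,
                   rtype = m$rtype %||% "UNSPECIFIED",
                   source = m$source %||% "gold")
  })
  corpus <- as_corpus(docs, preserve_identifiers)
  if (nrow(mentions)) validate_mentions(mentions, corpus)
  list(corpus = corpus, mentions = dplyr::bind_rows(.mention_cols(), mentions))
}

#' @rdname read_jsonl
#' @param corpus Corpus tibble.
#' @param mentions Mention tibble.
#' @export
write_jsonl <- function(corpus, mentions, path) {
  lines <- purrr::map_chr(seq_len(nrow(corpus)), function(i) {
    d <- corpus$doc_id[i]
    m <- mentions[mentions$doc_id == d,
                  c("start", "end", "surface", "rtype", "source"), drop = FALSE]
    jsonlite::toJSON(list(doc_id = d, title = corpus$title[i],
                          text = corpus$text[i], mentions = m),
                     auto_unbox = TRUE, dataframe = "rows")
  })
  writeLines(lines, path)
  invisible(path)
}
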