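# Linear-chain sequence tagger over B-I-O labels.
#
# The learner is an averaged structured perceptron with first-order
# transitions and Viterbi decoding — a discriminative linear-chain model
# trained on the same windowed feature vectors a CRF would consume.  It is
# deterministic given the seed, trains in seconds on corpus sizes used
# here, and persists to a plain-text artifact directory.

.LABELS <- c("B", "I", "O")

# Featurise a whole corpus into per-sentence lists of feature-string vectors.
.featurise_corpus <- function(corpus, dict, config) {
  purrr::map(seq_len(nrow(corpus)), function(i) {
    toks <- corpus$tokens[[i]]
    fs <- .feature_strings(token_features(toks, dict, config))
    split(fs, toks$sent)
  })
}

.viterbi <- function(emit, trans, start) {
  # emit: T x 3 matrix of label scores; trans: 3 x 3 (from x to); start: 3
  T_ <- nrow(emit)
  if (T_ == 0) return(character())
  delta <- matrix(-Inf, T_, 3)
  back <- matrix(0L, T_, 3)
  delta[1, ] <- start + emit[1, ]
  if (T_ > 1) {
    for (t in 2:T_) {
      for (y in 1:3) {
        sc <- delta[t - 1, ] + trans[, y]
        back[t, y] <- which.max(sc)
        delta[t, y] <- sc[back[t, y]] + emit[t, y]
      }
    }
  }
  path <- integer(T_)
  path[T_] <- which.max(delta[T_, ])
  if (T_ > 1) for (t in (T_ - 1):1) path[t] <- back[t + 1, path[t + 1]]
  .LABELS[path]
}

.emit_scores <- function(ids_list, W) {
  emit <- matrix(0, length(ids_list), 3)
  for (t in seq_along(ids_list)) {
    ids <- ids_list[[t]]
    if (length(ids)) emit[t, ] <- colSums(W[ids, , drop = FALSE])
  }
  emit
}

#' Train the sequence tagger
#'
#' Fits an averaged structured perceptron (linear-chain, first-order
#' transitions, Viterbi decoding) on B-I-O labelled documents.  Sentences
#' are shuffled each epoch under the given seed, so training is exactly
#' reproducible; the averaged weights make the model insensitive to the
#' final epoch's ordering noise.
#'
#' @param corpus Corpus tibble.
#' @param labels Flat label tibble from [bio_labels()].
#' @param dict Optional `resource_dictionary` for dictionary features.
#' @param config A [feature_config()].
#' @param epochs Training epochs (default 8).
#' @param seed Integer seed controlling sentence shuffling.
#' @return A `resner_tagger` object holding the feature vocabulary, weight
#'   matrices and the training configuration.
#' @export
train_tagger <- function(corpus, labels, dict = NULL, config = feature_config(),
                         epochs = 8L, seed = 1L) {
  if (nrow(corpus) == 0) stop("cannot train on an empty corpus", call. = FALSE)
  if (!any(labels$label %in% c("B", "I"))) {
    stop("corpus contains no positive (B/I) labels; nothing learnable", call. = FALSE)
  }
  feats <- .featurise_corpus(corpus, dict, config)
  lab_by_doc <- split(labels$label[order(labels$doc_id, labels$token_id)],
                      labels$doc_id[order(labels$doc_id, labels$token_id)])
  sents <- list(); ylist <- list()
  for (i in seq_len(nrow(corpus))) {
    d <- corpus$doc_id[i]
    toks <- corpus$tokens[[i]]
    y <- lab_by_doc[[d]]
    if (is.null(y) || length(y) != nrow(toks)) {
      stop("labels missing or misaligned for document ", d, call. = FALSE)
    }
    ys <- split(y, toks$sent)
    for (s in names(feats[[i]])) {
      sents[[length(sents) + 1L]] <- feats[[i]][[s]]
      ylist[[length(ylist) + 1L]] <- ys[[s]]
    }
  }
  vocab <- unique(unlist(sents, use.names = FALSE))
  ids_all <- purrr::map(sents, function(s) purrr::map(s, ~ match(.x, vocab)))
  W <- matrix(0, length(vocab), 3)
  Wu <- matrix(0, length(vocab), 3)
  trans <- matrix(0, 3, 3); transu <- matrix(0, 3, 3)
  start <- numeric(3); startu <- numeric(3)
  cnt <- 1
  old <- .save_seed()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(sents))
    for (si in ord) {
      ids <- ids_all[[si]]
      gold <- ylist[[si]]
      pred <- .viterbi(.emit_scores(ids, W), trans, start)
      if (!identical(pred, gold)) {
        gi <- match(gold, .LABELS); pi <- match(pred, .LABELS)
        for (t in seq_along(ids)) {
          if (gi[t] != pi[t]) {
            f <- ids[[t]]
            W[f, gi[t]] <- W[f, gi[t]] + 1; Wu[f, gi[t]] <- Wu[f, gi[t]] + cnt
            W[f, pi[t]] <- W[f, pi[t]] - 1; Wu[f, pi[t]] <- Wu[f, pi[t]] - cnt
          }
        }
        if (gi[1] != pi[1]) {
          start[gi[1]] <- start[gi[1]] + 1; startu[gi[1]] <- startu[gi[1]] + cnt
          start[pi[1]] <- start[pi[1]] - 1; startu[pi[1]] <- startu[pi[1]] - cnt
        }
        if (length(ids) > 1) {
          for (t in 2:length(ids)) {
            if (gi[t - 1] != pi[t - 1] || gi[t] != pi[t]) {
              trans[gi[t - 1], gi[t]] <- trans[gi[t - 1], gi[t]] + 1
              transu[gi[t - 1], gi[t]] <- transu[gi[t - 1], gi[t]] + cnt
              trans[pi[t - 1], pi[t]] <- trans[pi[t - 1], pi[t]] - 1
              transu[pi[t - 1], pi[t]] <- transu[pi[t - 1], pi[t]] - cnt
            }
          }
        }
      }
      cnt <- cnt + 1
    }
  }
  structure(list(
    vocab = vocab,
    W = W - Wu / cnt,
    trans = trans - transu / cnt,
    start = start - startu / cnt,
    config = config, epochs = as.integer(epochs), seed = as.integer(seed),
    uses_dict = !is.null(dict)
  ), class = "resner_tagger")
}

#' @export
print.resner_tagger <- function(x, ...) {
  cat(sprintf("<resner_tagger> %d features, window {%s}, groups {%s}, %d epochs, seed %d\n",
              length(x$vocab), paste(x$config$window, collapse = ","),
              paste(x$config$groups, collapse = ","), x$epochs, x$seed))
  invisible(x)
}

#' Tag a corpus with a trained model
#'
#' Decodes every sentence with Viterbi and repairs any invalid `I` labels
#' via [repair_bio()].  Features unseen in training are ignored (their
#' weight is zero).
#'
#' @param corpus Corpus tibble.
#' @param model A `resner_tagger`.
#' @param dict The dictionary used at training time (required when the
#'   model was trained with dictionary features).
#' @return A flat label tibble (`doc_id`, `token_id`, `label`).
#' @export
tag_corpus <- function(corpus, model, dict = NULL) {
  if (model$uses_dict && is.null(dict) &&
      "dictionary" %in% model$config$groups) {
    stop("model was trained with dictionary features; supply `dict`", call. = FALSE)
  }
  purrr::map_dfr(seq_len(nrow(corpus)), function(i) {
    toks <- corpus$tokens[[i]]
    if (!nrow(toks)) {
      return(tibble::tibble(doc_id = character(), token_id = integer(),
                            label = character()))
    }
    fs <- .feature_strings(token_features(toks, dict, model$config))
    lab <- character(nrow(toks))
    for (s in unique(toks$sent)) {
      idx <- which(toks$sent == s)
      ids <- purrr::map(fs[idx], function(f) {
        m <- match(f, model$vocab); m[!is.na(m)]
      })
      lab[idx] <- .viterbi(.emit_scores(ids, model$W), model$trans, model$start)
    }
    tibble::tibble(doc_id = corpus$doc_id[i], token_id = toks$token_id,
                   label = repair_bio(lab, toks$sent))
  })
}

#' Persist / restore a tagger model
#'
#' The artifact is a directory of plain text: `weights.tsv` (one row per
#' feature with its three label weights at full precision),
#' `transitions.tsv`, and a `config.json` sidecar recording the window,
#' feature groups, epochs and seed.  `load_tagger()` restores a model whose
#' tagging output is identical to the saved one.
#'
#' @param model A `resner_tagger`.
#' @param dir Artifact directory.
#' @return `save_tagger()` invisibly `dir`; `load_tagger()` the model.
#' @export
save_tagger <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  num <- function(x) sprintf("%.17g", x)
  writeLines(c("feature\tB\tI\tO",
               sprintf("%s\t%s\t%s\t%s", model$vocab,
                       num(model$W[, 1]), num(model$W[, 2]), num(model$W[, 3]))),
             file.path(dir, "weights.tsv"))
  writeLines(c(paste(num(model$start), collapse = "\t"),
               apply(model$trans, 1, function(r) paste(num(r), collapse = "\t"))),
             file.path(dir, "transitions.tsv"))
  jsonlite::write_json(
    list(backend = "averaged_structured_perceptron",
         labels = .LABELS, window = model$config$window,
         groups = model$config$groups, epochs = model$epochs,
         seed = model$seed, uses_dict = model$uses_dict,
         n_features = length(model$vocab)),
    file.path(dir, "config.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_tagger
#' @export
load_tagger <- function(dir) {
  cfg <- jsonlite::fromJSON(file.path(dir, "config.json"))
  wl <- readLines(file.path(dir, "weights.tsv"))[-1]
  parts <- strsplit(wl, "\t", fixed = TRUE)
  vocab <- purrr::map_chr(parts, 1)
  W <- matrix(as.numeric(unlist(purrr::map(parts, ~ .x[2:4]))),
              ncol = 3, byrow = TRUE)
  tl <- strsplit(readLines(file.path(dir, "transitions.tsv")), "\t", fixed = TRUE)
  start <- as.numeric(tl[[1]])
  trans <- matrix(as.numeric(unlist(tl[2:4])), ncol = 3, byrow = TRUE)
  structure(list(
    vocab = vocab, W = W, trans = trans, start = start,
    config = feature_config(window = cfg$window, groups = cfg$groups),
    epochs = cfg$epochs, seed = cfg$seed, uses_dict = cfg$uses_dict
  ), class = "resner_tagger")
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
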