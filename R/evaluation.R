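# Mention-level evaluation: strict and lenient matching, precision /
# recall / F, document-level k-fold cross-validation with macro and micro
# summaries, feature ablation, and inter-annotator agreement.

#' Precision, recall and F-score from counts
#'
#' Percentages; a zero denominator yields 0 by convention.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return A one-row tibble `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f_score`.
#' @examples
#' prf(3, 1, 1)
#' @export
prf <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  p <- if (tp + fp == 0) 0 else 100 * tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else 100 * tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  tibble::tibble(tp = tp, fp = fp, fn = fn,
                 precision = p, recall = r, f_score = f)
}

.overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

#' Compare predicted mentions against gold
#'
#' Strict mode: a prediction is a true positive iff its `(start, end)`
#' offsets exactly equal a gold mention's in the same document.  Lenient
#' mode: any character overlap counts, with greedy one-to-one pairing in
#' gold order so each gold and each prediction is used at most once.
#'
#' @param gold,pred Mention tibbles (non-overlapping within each document).
#' @param mode `"strict"` or `"lenient"`.
#' @return A one-row tibble: `mode`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f_score`.
#' @export
compare_mentions <- function(gold, pred, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  for (nm in c("gold", "pred")) {
    m <- if (nm == "gold") gold else pred
    if (nrow(m) > 1) {
      ms <- dplyr::arrange(m, .data$doc_id, .data$start)
      same <- ms$doc_id[-1] == ms$doc_id[-nrow(ms)]
      if (any(same & ms$start[-1] < ms$end[-nrow(ms)])) {
        stop("overlapping ", nm, " mentions; repair upstream", call. = FALSE)
      }
    }
  }
  tp <- 0L
  docs <- union(unique(gold$doc_id), unique(pred$doc_id))
  for (d in docs) {
    g <- dplyr::arrange(gold[gold$doc_id == d, ], .data$start)
    p <- dplyr::arrange(pred[pred$doc_id == d, ], .data$start)
    if (!nrow(g) || !nrow(p)) next
    if (mode == "strict") {
      tp <- tp + sum(paste(g$start, g$end) %in% paste(p$start, p$end))
    } else {
      used <- rep(FALSE, nrow(p))
      for (i in seq_len(nrow(g))) {
        hit <- which(!used & .overlaps(g$start[i], g$end[i], p$start, p$end))
        if (length(hit)) {
          used[hit[1]] <- TRUE
          tp <- tp + 1L
        }
      }
    }
  }
  res <- prf(tp, nrow(pred) - tp, nrow(gold) - tp)
  tibble::tibble(mode = mode, res)
}

#' Evaluate in both modes at once
#'
#' @inheritParams compare_mentions
#' @return A two-row tibble (strict and lenient).
#' @export
evaluate_mentions <- function(gold, pred) {
  dplyr::bind_rows(compare_mentions(gold, pred, "strict"),
                   compare_mentions(gold, pred, "lenient"))
}

#' Document-level k-fold assignment
#'
#' Seeded shuffle followed by round-robin assignment: fold sizes differ by
#' at most one and no document appears in two folds.
#'
#' @param doc_ids Character vector of document ids.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return A tibble `doc_id`, `fold` (1..k).
#' @export
kfold_split <- function(doc_ids, k = 5L, seed = 1L) {
  doc_ids <- unique(as.character(doc_ids))
  if (k > length(doc_ids)) {
    stop(sprintf("k = %d exceeds the number of documents (%d)", k, length(doc_ids)),
         call. = FALSE)
  }
  old <- .save_seed()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  shuffled <- sample(doc_ids)
  tibble::tibble(doc_id = shuffled,
                 fold = rep_len(seq_len(k), length(shuffled))) |>
    dplyr::arrange(.data$doc_id)
}

#' Cross-validated evaluation of the dictionary baseline and the tagger
#'
#' For each fold: the dictionary baseline is evaluated on the held-out test
#' documents only (it needs no training); the sequence tagger is trained on
#' the remaining k-1 folds, applied to the held-out fold, and optionally
#' post-processed (transductive votes collected over the held-out fold
#' being tagged).  Both strict and lenient scores are reported per fold,
#' with min / max / mean (macro) and micro-average (pooled counts)
#' summaries.
#'
#' @param corpus Corpus tibble.
#' @param mentions Gold mention tibble.
#' @param dict A `resource_dictionary`.
#' @param k Number of folds (default 5).
#' @param seed Seed for the fold split and tagger training.
#' @param config A [feature_config()].
#' @param postprocess Apply the two-pass relabelling to tagger output.
#' @param systems Which systems to run: subset of `"dictionary"`, `"tagger"`.
#' @param epochs Tagger training epochs.
#' @param blacklist Second-pass blacklist.
#' @return A `resner_cv` object: list with `folds` (per-fold, per-system,
#'   per-mode scores), `summary` (Min/Max/Mean/Micro rows) and the fold
#'   assignment.  `tidy()` returns the per-fold rows, `glance()` the
#'   summary.
#' @export
cross_validate <- function(corpus, mentions, dict, k = 5L, seed = 1L,
                           config = feature_config(), postprocess = TRUE,
                           systems = c("dictionary", "tagger"),
                           epochs = 8L, blacklist = DEFAULT_BLACKLIST) {
  folds <- kfold_split(corpus$doc_id, k = k, seed = seed)
  rows <- list()
  for (f in seq_len(k)) {
    test_ids <- folds$doc_id[folds$fold == f]
    train_ids <- folds$doc_id[folds$fold != f]
    test_corpus <- corpus[corpus$doc_id %in% test_ids, , drop = FALSE]
    gold_test <- mentions[mentions$doc_id %in% test_ids, , drop = FALSE]
    zero_gold <- nrow(gold_test) == 0
    preds <- list()
    if ("dictionary" %in% systems) {
      preds$dictionary <- match_corpus(test_corpus, dict)
    }
    if ("tagger" %in% systems) {
      train_corpus <- corpus[corpus$doc_id %in% train_ids, , drop = FALSE]
      train_labels <- bio_labels(train_corpus,
                                 mentions[mentions$doc_id %in% train_ids, ])
      model <- train_tagger(train_corpus, train_labels, dict = dict,
                            config = config, epochs = epochs, seed = seed)
      lab <- tag_corpus(test_corpus, model, dict = dict)
      if (postprocess) lab <- postprocess_labels(test_corpus, lab, dict,
                                                 blacklist = blacklist)
      preds$tagger <- labels_to_mentions(test_corpus, lab)
    }
    for (sys in names(preds)) {
      ev <- evaluate_mentions(gold_test, preds[[sys]])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        fold = f, system = sys, ev, n_gold = nrow(gold_test),
        zero_gold_fold = zero_gold)
    }
  }
  folds_tbl <- dplyr::bind_rows(rows)
  summary <- folds_tbl |>
    dplyr::group_by(.data$system, .data$mode) |>
    dplyr::summarise(
      min_f = min(.data$f_score), max_f = max(.data$f_score),
      mean_precision = mean(.data$precision), mean_recall = mean(.data$recall),
      mean_f = mean(.data$f_score),
      micro_precision = prf(sum(.data$tp), sum(.data$fp), sum(.data$fn))$precision,
      micro_recall = prf(sum(.data$tp), sum(.data$fp), sum(.data$fn))$recall,
      micro_f = prf(sum(.data$tp), sum(.data$fp), sum(.data$fn))$f_score,
      .groups = "drop")
  structure(list(folds = folds_tbl, summary = summary, assignment = folds,
                 k = k, seed = seed, postprocess = postprocess),
            class = "resner_cv")
}

#' @export
print.resner_cv <- function(x, ...) {
  cat(sprintf("<resner_cv> %d folds, seed %d, post-processing %s\n",
              x$k, x$seed, if (x$postprocess) "on" else "off"))
  print(x$summary)
  invisible(x)
}

#' @rdname cross_validate
#' @param x A `resner_cv`.
#' @param ... Unused.
#' @export
tidy.resner_cv <- function(x, ...) x$folds

#' @rdname cross_validate
#' @export
glance.resner_cv <- function(x, ...) x$summary

#' Feature-group ablation
#'
#' Re-runs the tagger cross-validation once per configuration, dropping
#' each requested feature group in turn; post-processing is disabled so
#' contributions are not confounded by the dictionary-aware second pass.
#' All runs share the same fold assignment and seed.
#'
#' @param corpus,mentions,dict,k,seed,epochs As [cross_validate()].
#' @param drop_groups Character vector of groups to ablate (each produces
#'   one run); the baseline (drop nothing) is always included first.
#' @return A tibble of summary rows with a `dropped` column (`"none"` for
#'   the baseline).
#' @export
feature_ablation <- function(corpus, mentions, dict,
                             drop_groups = c("lexical", "syntactic",
                                             "orthographic", "dictionary"),
                             k = 5L, seed = 1L, epochs = 8L) {
  all_groups <- c("lexical", "orthographic", "dictionary", "syntactic")
  bad <- setdiff(drop_groups, all_groups)
  if (length(bad)) stop("unknown feature group: ", bad[1], call. = FALSE)
  configs <- c(list(none = all_groups),
               stats::setNames(purrr::map(drop_groups, ~ setdiff(all_groups, .x)),
                               drop_groups))
  purrr::imap_dfr(configs, function(groups, nm) {
    cv <- cross_validate(corpus, mentions, dict, k = k, seed = seed,
                         config = feature_config(groups = groups),
                         postprocess = FALSE, systems = "tagger",
                         epochs = epochs)
    tibble::tibble(dropped = nm, cv$summary)
  })
}

#' Inter-annotator agreement
#'
#' Scores annotator B's spans against annotator A's using the mention
#' evaluator, in both directions (the measure is asymmetric: precision and
#' recall swap roles when the reference annotator changes).
#'
#' @param annotations_a,annotations_b Mention tibbles over the same
#'   documents.
#' @return A tibble with `reference` (`"A"` or `"B"`) and both modes.
#' @export
iaa <- function(annotations_a, annotations_b) {
  if (!length(intersect(unique(annotations_a$doc_id),
                        unique(annotations_b$doc_id))) &&
      nrow(annotations_a) && nrow(annotations_b)) {
    stop("annotator document sets are disjoint", call. = FALSE)
  }
  dplyr::bind_rows(
    tibble::tibble(reference = "A", evaluate_mentions(annotations_a, annotations_b)),
    tibble::tibble(reference = "B", evaluate_mentions(annotations_b, annotations_a))
  )
}

#' Rounded summary view
#'
#' Scores are kept at full precision internally; this view rounds to whole
#' percentages for compact, report-style display.
#'
#' @param cv A `resner_cv`.
#' @return The summary tibble with integer-rounded score columns.
#' @export
summary_view <- function(cv) {
  dplyr::mutate(cv$summary,
                dplyr::across(dplyr::where(is.numeric), ~ round(.x)))
}
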