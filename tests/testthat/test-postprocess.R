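# Build a small corpus with hand-set pass-1 labels for promotion tests.
pp_fixture <- function() {
  texts <- c(
    d1 = "FOOBAR was fast . FOOBAR again . we saw FOOBAR analysis once",
    d2 = "FOOBAR appeared here . analysis was done . analysis again",
    d3 = "the analysis step used analysis and analysis tools")
  corpus <- toy_corpus(texts)
  labels <- bio_labels(corpus, resner:::.mention_cols())  # all O
  # pass 1: FOOBAR tagged B in d1 (first three) => 3 labelled, then O in d2
  set_label <- function(labels, doc, surface, corpus, which_occ, value) {
    toks <- corpus$tokens[[match(doc, corpus$doc_id)]]
    occ <- which(toks$text == surface)[which_occ]
    labels$label[labels$doc_id == doc & labels$token_id %in% occ] <- value
    labels
  }
  labels <- set_label(labels, "d1", "FOOBAR", corpus, 1:3, "B")
  # "analysis": labelled everywhere (5 times) but blacklisted
  labels <- set_label(labels, "d2", "analysis", corpus, 1:2, "B")
  labels <- set_label(labels, "d3", "analysis", corpus, 1:3, "B")
  list(corpus = corpus, labels = labels)
}

test_that("vote collection counts labelled vs unlabelled per exact surface", {
  fx <- pp_fixture()
  votes <- collect_token_votes(fx$corpus, fx$labels)
  foo <- votes[votes$surface == "FOOBAR", ]
  expect_equal(foo$labelled, 3L)
  expect_equal(foo$unlabelled, 1L)
  expect_false("missingtoken" %in% votes$surface)
  expect_equal(sum(votes$labelled + votes$unlabelled),
               sum(purrr::map_int(fx$corpus$tokens, nrow)))

  all_o <- fx$labels
  all_o$label <- "O"
  v0 <- collect_token_votes(fx$corpus, all_o)
  expect_true(all(v0$labelled == 0L))
})

test_that("acronym eligibility requires caps only, no digits, length two plus", {
  expect_true(acronym_eligible("AB"))
  expect_false(acronym_eligible("A1"))
  expect_false(acronym_eligible("A"))
  expect_true(acronym_eligible("CLUSTALW"))
  expect_false(acronym_eligible("MySQL"))
})

test_that("promotion needs majority vote, dict-or-acronym, and no blacklist hit", {
  fx <- pp_fixture()
  votes <- collect_token_votes(fx$corpus, fx$labels)
  dict <- toy_dict(c("analysis", "SW"))
  out <- second_pass_relabel(fx$corpus, fx$labels, votes, dict)

  # FOOBAR: votes (3,1), acronym-eligible -> the d2 occurrence is promoted
  d2_toks <- fx$corpus$tokens[[2]]
  foo_id <- d2_toks$token_id[d2_toks$text == "FOOBAR"]
  expect_equal(out$label[out$doc_id == "d2" & out$token_id == foo_id], "B")

  # analysis: majority vote (5 labelled, 1 not) and in dict, but
  # blacklisted -> the O occurrence in d1 is never promoted
  d1_toks <- fx$corpus$tokens[[1]]
  ana_id <- d1_toks$token_id[d1_toks$text == "analysis"]
  expect_equal(out$label[out$doc_id == "d1" & out$token_id == ana_id], "O")

  # existing labels never removed
  j <- dplyr::inner_join(fx$labels, out, by = c("doc_id", "token_id"),
                         suffix = c("_before", "_after"))
  expect_false(any(j$label_before != "O" & j$label_after == "O"))
})

test_that("a tied vote rejects promotion", {
  texts <- c(d1 = "TOOL ran . TOOL ran", d2 = "nothing here")
  corpus <- toy_corpus(texts)
  labels <- bio_labels(corpus, resner:::.mention_cols())
  t1 <- corpus$tokens[[1]]
  first <- t1$token_id[t1$text == "TOOL"][1]
  labels$label[labels$doc_id == "d1" & labels$token_id == first] <- "B"
  votes <- collect_token_votes(corpus, labels)
  expect_equal(votes$labelled[votes$surface == "TOOL"], 1L)
  expect_equal(votes$unlabelled[votes$surface == "TOOL"], 1L)
  out <- second_pass_relabel(corpus, labels, votes, toy_dict())
  expect_identical(out$label, labels$label)
})

test_that("relabelling is idempotent under fixed votes and never lowers recall", {
  set.seed(17)
  g <- synth_world(n_docs = 8, seed = 17)
  labels <- bio_labels(g$corpus, g$mentions)
  # degrade: flip 40 % of positive labels to O to emulate pass-1 misses
  pos <- which(labels$label != "O")
  drop <- sample(pos, floor(0.4 * length(pos)))
  noisy <- labels
  noisy$label[drop] <- "O"
  noisy$label <- unlist(purrr::map(split(noisy$label, noisy$doc_id), repair_bio),
                        use.names = FALSE)

  votes <- collect_token_votes(g$corpus, noisy)
  once <- second_pass_relabel(g$corpus, noisy, votes, g$dictionary)
  twice <- second_pass_relabel(g$corpus, once, votes, g$dictionary)
  expect_identical(once$label, twice$label)

  recall_tok <- function(lab) {
    j <- dplyr::inner_join(lab, labels, by = c("doc_id", "token_id"),
                           suffix = c("_p", "_g"))
    mean(j$label_p[j$label_g != "O"] != "O")
  }
  expect_gte(recall_tok(once), recall_tok(noisy))
})

test_that("second pass equals a literal brute-force re-check on small corpora", {
  set.seed(23)
  for (s in c(23, 24, 25)) {
    g <- synth_world(n_docs = 5, seed = s)
    labels <- bio_labels(g$corpus, g$mentions)
    pos <- which(labels$label != "O")
    labels$label[sample(pos, floor(length(pos) / 2))] <- "O"
    labels$label <- unlist(purrr::map(split(labels$label, labels$doc_id), repair_bio),
                           use.names = FALSE)
    votes <- collect_token_votes(g$corpus, labels)
    got <- second_pass_relabel(g$corpus, labels, votes, g$dictionary)
    want <- brute_second_pass(g$corpus, labels, g$dictionary, DEFAULT_BLACKLIST)
    expect_equal(got$label, want, info = paste("seed", s))
  }
})
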