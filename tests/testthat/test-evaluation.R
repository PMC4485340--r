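test_that("precision, recall and F follow their definitions with 0/0 -> 0", {
  r <- prf(3, 1, 1)
  expect_equal(c(r$precision, r$recall, r$f_score), c(75, 75, 75))
  r0 <- prf(0, 0, 0)
  expect_equal(c(r0$precision, r0$recall, r0$f_score), c(0, 0, 0))
  r1 <- prf(1, 0, 0)
  expect_equal(c(r1$precision, r1$recall, r1$f_score), c(100, 100, 100))
})

test_that("strict matching needs exact offsets, lenient needs overlap", {
  g <- new_mentions("d", 5, 10, "BLAST")
  p <- new_mentions("d", 5, 10, "BLAST", source = "crf")
  expect_equal(compare_mentions(g, p, "strict")$tp, 1L)

  g2 <- new_mentions("d", 0, 13, "Gene Ontology")
  p2 <- new_mentions("d", 0, 4, "Gene", source = "crf")
  s <- compare_mentions(g2, p2, "strict")
  expect_equal(c(s$tp, s$fp, s$fn), c(0L, 1L, 1L))
  l <- compare_mentions(g2, p2, "lenient")
  expect_equal(l$tp, 1L)

  empty <- resner:::.mention_cols()
  g3 <- dplyr::bind_rows(new_mentions("d", 0, 2, "ab"), new_mentions("d", 5, 7, "cd"),
                         new_mentions("d", 9, 11, "ef"))
  e <- compare_mentions(g3, empty, "strict")
  expect_equal(e$fn, 3L)
  expect_equal(e$recall, 0)
})

test_that("lenient pairing is one-to-one", {
  # one long prediction overlapping two golds counts only once
  g <- dplyr::bind_rows(new_mentions("d", 0, 4, "aaaa"), new_mentions("d", 6, 10, "bbbb"))
  p <- new_mentions("d", 0, 10, "aaaa bbbbb", source = "crf")
  l <- compare_mentions(g, p, "lenient")
  expect_equal(c(l$tp, l$fp, l$fn), c(1L, 0L, 1L))
})

test_that("overlapping predictions are rejected", {
  g <- new_mentions("d", 0, 4, "aaaa")
  p <- dplyr::bind_rows(new_mentions("d", 0, 4, "aaaa"), new_mentions("d", 2, 6, "aa b"))
  expect_error(compare_mentions(g, p, "strict"), "overlapping")
})

test_that("tp is symmetric under gold/pred swap, fp and fn trade places", {
  set.seed(13)
  g <- synth_world(n_docs = 5, seed = 13)
  pred <- match_corpus(g$corpus, g$dictionary)
  for (mode in c("strict", "lenient")) {
    a <- compare_mentions(g$mentions, pred, mode)
    b <- compare_mentions(pred, g$mentions, mode)
    expect_equal(a$tp, b$tp)
    expect_equal(a$fp, b$fn)
    expect_equal(a$fn, b$fp)
  }
})

test_that("lenient scores dominate strict scores on arbitrary predictions", {
  set.seed(19)
  g <- synth_world(n_docs = 6, seed = 19)
  for (rep in 1:5) {
    pred <- purrr::map_dfr(seq_len(nrow(g$corpus)), function(i) {
      random_mentions(g$corpus$tokens[[i]], g$corpus$text[i],
                      g$corpus$doc_id[i], n = sample(0:5, 1))
    })
    s <- compare_mentions(g$mentions, pred, "strict")
    l <- compare_mentions(g$mentions, pred, "lenient")
    expect_gte(l$tp, s$tp)
    expect_gte(l$precision, s$precision)
    expect_gte(l$recall, s$recall)
    expect_gte(l$f_score, s$f_score)
  }
})

test_that("k-fold split is balanced, seeded and document-level", {
  f <- kfold_split(paste0("d", 1:10), k = 5, seed = 3)
  expect_equal(as.integer(sort(table(f$fold))), rep(2L, 5))
  expect_identical(f, kfold_split(paste0("d", 1:10), k = 5, seed = 3))
  f11 <- kfold_split(paste0("d", 1:11), k = 5, seed = 3)
  expect_equal(as.integer(sort(table(f11$fold), decreasing = TRUE)),
               c(3L, 2L, 2L, 2L, 2L))
  expect_equal(anyDuplicated(f11$doc_id), 0L)
  expect_error(kfold_split(paste0("d", 1:3), k = 5), "exceeds")
})

test_that("macro mean and micro average differ exactly on unbalanced folds", {
  # two folds with (tp, fp, fn) = (1,0,1) and (3,0,1):
  # mean recall (50 + 75)/2 = 62.5, micro recall 4/6 = 66.7
  r1 <- prf(1, 0, 1); r2 <- prf(3, 0, 1)
  expect_equal(mean(c(r1$recall, r2$recall)), 62.5)
  micro <- prf(1 + 3, 0, 1 + 1)
  expect_equal(micro$recall, 100 * 4 / 6, tolerance = 1e-12)

  # the same arithmetic through cross_validate on a constructed corpus:
  # each fold has one document; dictionary misses exactly the novel names
  texts <- c(a = "AlphaTool ran and NovelOne ran",
             b = "BetaTool ran . GammaTool ran . DeltaTool ran . NovelTwo ran")
  corpus <- toy_corpus(texts)
  gold <- dplyr::bind_rows(
    new_mentions("a", 0, 9, "AlphaTool"), new_mentions("a", 18, 26, "NovelOne"),
    new_mentions("b", 0, 8, "BetaTool"), new_mentions("b", 15, 24, "GammaTool"),
    new_mentions("b", 31, 40, "DeltaTool"), new_mentions("b", 47, 55, "NovelTwo"))
  dict <- toy_dict(c("AlphaTool", "SW"), c("BetaTool", "SW"),
                   c("GammaTool", "SW"), c("DeltaTool", "SW"))
  cv <- cross_validate(corpus, gold, dict, k = 2, seed = 1,
                       systems = "dictionary")
  s <- cv$summary[cv$summary$mode == "strict", ]
  expect_equal(s$mean_recall, 62.5)
  expect_equal(s$micro_recall, 100 * 4 / 6, tolerance = 1e-12)
})

test_that("cross-validation is reproducible given a seed", {
  g <- synth_world(n_docs = 8, seed = 29)
  cv1 <- cross_validate(g$corpus, g$mentions, g$dictionary, k = 4, seed = 2,
                        epochs = 2)
  cv2 <- cross_validate(g$corpus, g$mentions, g$dictionary, k = 4, seed = 2,
                        epochs = 2)
  expect_identical(cv1$folds, cv2$folds)
  expect_s3_class(tidy(cv1), "tbl_df")
  expect_s3_class(glance(cv1), "tbl_df")
})

test_that("inter-annotator agreement is scored in both directions", {
  a <- dplyr::bind_rows(new_mentions("d", 0, 4, "aaaa"), new_mentions("d", 6, 10, "bbbb"))
  r <- iaa(a, a)
  expect_true(all(r$f_score == 100))

  # widen every span by one token on one side: strict F = 0, lenient F = 100
  txt <- "aaaa x bbbb y"
  b <- dplyr::bind_rows(new_mentions("d", 0, 6, "aaaa x"),
                        new_mentions("d", 6, 13, "bbbb y"))
  # b overlaps a's spans but never equals them
  r2 <- iaa(a, b)
  expect_true(all(r2$f_score[r2$mode == "strict"] == 0))
  expect_true(all(r2$f_score[r2$mode == "lenient"] == 100))

  r3 <- iaa(a, resner:::.mention_cols()[0, ])
  expect_true(all(r3$f_score == 0))
})

test_that("ablation includes a baseline and errors on unknown groups", {
  g <- synth_world(n_docs = 6, seed = 37)
  ab <- feature_ablation(g$corpus, g$mentions, g$dictionary,
                         drop_groups = "syntactic", k = 2, seed = 1, epochs = 2)
  expect_setequal(unique(ab$dropped), c("none", "syntactic"))
  expect_equal(nrow(ab), 2L * 2L)  # two configs x two modes
  expect_error(feature_ablation(g$corpus, g$mentions, g$dictionary,
                                drop_groups = "bogus", k = 2), "unknown feature group")
})
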