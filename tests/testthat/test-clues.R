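clue_doc <- function(txt) {
  list(tokens = tokenize_text(txt), text = txt)
}

test_that("head terms yield adjacent name-shaped candidates", {
  d <- clue_doc("the stochastic simulator Dizzy allows rapid testing")
  h <- detect_head_terms(d$tokens, d$text)
  expect_equal(h$clue, "simulator")
  expect_equal(h$candidate, "Dizzy")

  d2 <- clue_doc("The MethMarker software was applied")
  h2 <- detect_head_terms(d2$tokens, d2$text)
  expect_equal(h2$candidate, "MethMarker")

  d3 <- clue_doc("biological systems are complex")
  h3 <- detect_head_terms(d3$tokens, d3$text)
  expect_true(nrow(h3) == 0 || all(is.na(h3$candidate)))
})

test_that("Hearst enumerations return every list member", {
  d <- clue_doc("we used tools : CLUSTALW , Muscle3 , and MUSCLE .")
  h <- detect_hearst(d$tokens, d$text)
  expect_setequal(h$candidate, c("CLUSTALW", "Muscle3", "MUSCLE"))

  d2 <- clue_doc("programs such as Simlink , SimCoal , and SimPed .")
  h2 <- detect_hearst(d2$tokens, d2$text)
  expect_true(all(c("Simlink", "SimPed") %in% h2$candidate))

  d3 <- clue_doc("we used many things yesterday")
  expect_equal(nrow(detect_hearst(d3$tokens, d3$text)), 0L)
})

test_that("title pattern extracts short name-shaped pre-colon names", {
  expect_equal(detect_title_pattern(
    "CoXpress: differential co-expression in gene expression data"), "CoXpress")
  expect_equal(detect_title_pattern(
    "SimHap GUI: An intuitive graphical user interface for genetic association analysis"),
    "SimHap GUI")
  expect_true(is.na(detect_title_pattern("A comparison of methods")))
  # method/algorithm guard
  expect_true(is.na(detect_title_pattern(
    "A method: for doing something")))
})

test_that("version clues attach to the preceding name and skip hardware specs", {
  d <- clue_doc("CLUSTAL W version 1.83 was applied")
  v <- detect_version(d$tokens, d$text)
  expect_equal(v$candidate, "CLUSTAL W")
  expect_equal(v$clue, "1.83")

  d2 <- clue_doc("using dot v1.10 and settings")
  v2 <- detect_version(d2$tokens, d2$text)
  expect_equal(v2$candidate, "dot")
  expect_equal(v2$clue, "1.10")

  d3 <- clue_doc("an AMD Athlon 1.8 GHz processor was used")
  expect_equal(nrow(detect_version(d3$tokens, d3$text)), 0L)
})

test_that("reference and URL adjacency admits only name-shaped candidates", {
  d <- clue_doc("Galaxy [18] and EpiGRAPH [19] were used")
  r <- detect_ref_url(d$tokens, d$text)
  expect_setequal(r$candidate, c("Galaxy", "EpiGRAPH"))

  d2 <- clue_doc("The learning metrics principle [14, 15] was used")
  expect_equal(nrow(detect_ref_url(d2$tokens, d2$text)), 0L)

  d3 <- clue_doc("no citations appear here")
  expect_equal(nrow(detect_ref_url(d3$tokens, d3$text)), 0L)
})

test_that("comparison cues pair name-shaped sides", {
  d <- clue_doc("xPedPhase did better than i Linker overall")
  cmp <- detect_comparison(d$tokens, d$text)
  expect_equal(cmp$candidate, "xPedPhase")
  expect_equal(cmp$candidate2, "i Linker")

  d2 <- clue_doc("Like Moleculizer , Tabasco dynamically generates models")
  cmp2 <- detect_comparison(d2$tokens, d2$text)
  expect_equal(cmp2$candidate, "Moleculizer")
  expect_equal(cmp2$candidate2, "Tabasco")

  d3 <- clue_doc("this was better than that")
  expect_equal(nrow(detect_comparison(d3$tokens, d3$text)), 0L)
})

test_that("detectors are pure functions of their input", {
  d <- clue_doc("the simulator Dizzy ran faster than SimPed v2.1 [3]")
  expect_identical(detect_head_terms(d$tokens, d$text),
                   detect_head_terms(d$tokens, d$text))
  expect_identical(detect_clues(toy_corpus(c(a = d$text))),
                   detect_clues(toy_corpus(c(a = d$text))))
})

test_that("clue co-occurrence computes forward and reverse fractions", {
  texts <- c(
    d1 = "we ran ToolA here . we ran it again . nothing else",
    d2 = "we ran ToolB there . we ran nothing")
  corpus <- toy_corpus(texts)
  gold <- dplyr::bind_rows(
    new_mentions("d1", 7, 12, "ToolA"),
    new_mentions("d2", 7, 12, "ToolB"))
  st <- clue_cooccurrence(corpus, gold, "\\bran\\b")
  expect_equal(st$n_clue_sentences, 4L)
  expect_equal(st$n_clue_sentences_with_mention, 2L)
  expect_equal(st$forward_fraction, 0.5)

  none <- clue_cooccurrence(corpus, gold, "zzzz")
  expect_true(none$no_match)
  expect_equal(none$forward_fraction, 0)

  both <- clue_cooccurrence(corpus[1, ], gold[1, ], "ToolA|ran")
  # in d1 all "ran" sentences: s1 has mention; forward < 1 here, so use a
  # corpus where every sentence has both
  single <- toy_corpus(c(x = "we ran ToolC today"))
  gm <- new_mentions("x", 7, 12, "ToolC")
  all1 <- clue_cooccurrence(single, gm, "ran")
  expect_equal(all1$forward_fraction, 1)
  expect_equal(all1$reverse_fraction, 1)
})

test_that("clue candidates add recall for novel names in clue contexts", {
  dict <- make_toy_dictionary(20, seed = 101)
  g <- generate_corpus(synth_config(n_docs = 12, novel_name_rate = 0.6,
                                    ambiguity_rate = 0, clue_context_rate = 1,
                                    seed = 101), dict)
  dict_pred <- match_corpus(g$corpus, g$dictionary)
  base <- compare_mentions(g$mentions, dict_pred, "lenient")

  clues <- detect_clues(g$corpus)
  cand <- clues[!is.na(clues$cand_start),
                c("doc_id", "cand_start", "cand_end", "candidate")]
  cand <- dplyr::distinct(
    tibble::tibble(doc_id = cand$doc_id, start = cand$cand_start,
                   end = cand$cand_end, surface = cand$candidate,
                   rtype = "UNSPECIFIED", source = "clue"))
  # union with dictionary matches, dropping overlaps greedily
  merged <- dplyr::arrange(dplyr::bind_rows(dict_pred, cand), doc_id, start,
                           dplyr::desc(end))
  keep <- purrr::map_dfr(split(merged, merged$doc_id), function(m) {
    pos <- -1
    m[purrr::map_lgl(seq_len(nrow(m)), function(i) {
      if (m$start[i] >= pos) { pos <<- m$end[i]; TRUE } else FALSE
    }), ]
  })
  with_clues <- compare_mentions(g$mentions, keep, "lenient")
  expect_gt(with_clues$recall, base$recall)
})
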