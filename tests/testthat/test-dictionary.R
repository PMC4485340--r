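test_that("dictionary TSV loading builds entries, variants and index", {
  f <- withr::local_tempfile(lines = c(
    "canonical\trtype\tsource\tvariants",
    "UniProt\tDB\tnar\tUniProt|Uniprot"))
  d <- read_dictionary(f)
  s <- dictionary_stats(d)
  expect_equal(s$n_entries, 1L)
  expect_equal(s$n_variants, 2L)

  empty <- withr::local_tempfile(lines = character())
  d0 <- read_dictionary(empty)
  expect_equal(dictionary_stats(d0)$n_entries, 0L)
  toks <- tokenize_text("nothing to see")
  expect_equal(nrow(match_dictionary(toks, d0, "nothing to see")), 0L)
})

test_that("a variant shared by two entries stays resolvable under both", {
  d <- toy_dict(c("Gene Ontology", "DB", "Gene Ontology|GO"),
                c("GO software", "SW", "GO software|GO"))
  hits <- d$variants$entry_id[d$variants$variant == "GO"]
  expect_setequal(hits, c(1L, 2L))
  # type conflict across owners -> UNSPECIFIED mention
  txt <- "we applied GO here"
  m <- match_dictionary(tokenize_text(txt), d, txt)
  expect_equal(m$surface, "GO")
  expect_equal(m$rtype, "UNSPECIFIED")
})

test_that("bad dictionary rows fail with informative errors", {
  expect_error(new_dictionary(tibble::tibble(canonical = "X", rtype = "XX")),
               "unknown rtype")
  expect_error(new_dictionary(tibble::tibble(canonical = "", rtype = "DB")),
               "blank canonical")
})

test_that("matching is leftmost-longest on token boundaries", {
  d <- toy_dict(c("BLAST", "SW"), c("Gene Ontology", "DB"), c("Gene", "DB"))
  txt <- "we ran BLAST against"
  m <- match_dictionary(tokenize_text(txt), d, txt)
  expect_equal(m$surface, "BLAST")

  txt2 <- "the Gene Ontology terms"
  m2 <- match_dictionary(tokenize_text(txt2), d, txt2)
  expect_equal(m2$surface, "Gene Ontology")  # longest wins over "Gene"
})

test_that("identifier tokenisation and suppression block GO:nnn false positives", {
  d <- toy_dict(c("GO", "DB"))
  txt <- "annotated with GO:0007089 here"
  m_on <- match_dictionary(tokenize_text(txt), d, txt)
  expect_equal(nrow(m_on), 0L)
  toks_off <- tokenize_text(txt, preserve_identifiers = FALSE)
  m_off <- match_dictionary(toks_off, d, txt, suppress_identifiers = FALSE)
  expect_equal(m_off$surface, "GO")
  m_sup <- match_dictionary(toks_off, d, txt, suppress_identifiers = TRUE)
  expect_equal(nrow(m_sup), 0L)
})

test_that("short and all-caps variants match case-sensitively, long mixed-case loosely", {
  d <- toy_dict(c("BLAST", "SW"), c("Gene Ontology", "DB"))
  txt <- "we blast the gene ontology"
  m <- match_dictionary(tokenize_text(txt), d, txt)
  expect_equal(m$surface, "gene ontology")   # long mixed-case: loose
  expect_false("blast" %in% m$surface)       # all-caps: strict
})

test_that("abbreviation detection pairs long forms with short forms", {
  txt <- "the Database of Interacting Proteins (DIP) stores interactions"
  p <- detect_abbreviations(tokenize_text(txt), txt)
  expect_equal(p$long_form, "Database of Interacting Proteins")
  expect_equal(p$short_form, "DIP")

  txt2 <- "about two percent (2 %) failed"
  expect_equal(nrow(detect_abbreviations(tokenize_text(txt2), txt2)), 0L)

  txt3 <- "no parentheses at all"
  expect_equal(nrow(detect_abbreviations(tokenize_text(txt3), txt3)), 0L)
})

test_that("document-local short forms extend matching when enabled", {
  d <- toy_dict(c("Database of Interacting Proteins", "DB"))
  txt <- "the Database of Interacting Proteins (DIP) stores data. DIP is large."
  toks <- tokenize_text(txt)
  off <- match_dictionary(toks, d, txt, expand_abbreviations = FALSE)
  on <- match_dictionary(toks, d, txt, expand_abbreviations = TRUE)
  expect_false("DIP" %in% off$surface)
  expect_true("DIP" %in% on$surface)
  expect_gt(nrow(on), nrow(off))
})

test_that("ambiguity report intersects names with word lists per case policy", {
  r <- ambiguity_report(c("analysis", "UniProt"),
                        english = c("analysis", "cycle"))
  expect_equal(r$n_overlap, 1L)
  expect_equal(r$matches[[1]], "analysis")

  r0 <- ambiguity_report(character(), english = c("a", "b"))
  expect_equal(r0$n_overlap, 0L)

  cs <- ambiguity_report(c("Blast"), english = c("blast"))
  ci <- ambiguity_report(c("Blast"), english = c("blast"), case_sensitive = FALSE)
  expect_equal(cs$n_overlap, 0L)
  expect_equal(ci$n_overlap, 1L)
})

test_that("matcher agrees with brute-force n-gram enumeration", {
  set.seed(7)
  d <- toy_dict(c("BLAST", "SW"), c("Gene Ontology", "DB", "Gene Ontology|GO"),
                c("Gene", "DB"), c("dot", "SW"), c("SimPed", "SW"))
  vocabulary <- c("we", "ran", "BLAST", "Gene", "Ontology", "GO", "dot",
                  "SimPed", "the", "and", "fast", "genes", ".")
  for (rep in 1:25) {
    txt <- paste(sample(vocabulary, sample(5:20, 1), replace = TRUE),
                 collapse = " ")
    toks <- tokenize_text(txt)
    got <- match_dictionary(toks, d, txt)
    want <- brute_match(toks, d, txt)
    expect_equal(nrow(got), nrow(want), info = txt)
    if (nrow(got)) {
      expect_equal(got$start, unname(want[, 1]), info = txt)
      expect_equal(got$end, unname(want[, 2]), info = txt)
    }
  }
})

test_that("matches never overlap and removing an entry never adds matches", {
  g <- synth_world(n_docs = 6, seed = 51)
  full <- match_corpus(g$corpus, g$dictionary)
  for (d in unique(full$doc_id)) {
    m <- dplyr::arrange(full[full$doc_id == d, ], start)
    if (nrow(m) > 1) expect_true(all(m$start[-1] >= m$end[-nrow(m)]))
  }
  ent <- g$dictionary$entries
  keep <- ent$entry_id[-1]
  smaller <- new_dictionary(tibble::tibble(
    canonical = ent$canonical[-1], rtype = ent$rtype[-1], source = ent$source[-1],
    variants = unname(split(g$dictionary$variants$variant,
                            g$dictionary$variants$entry_id)[as.character(keep)])))
  expect_lte(nrow(match_corpus(g$corpus, smaller)), nrow(full))
})
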