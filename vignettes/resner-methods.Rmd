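---
title: "Recognising database and software mentions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognising database and software mentions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resner)
```

## The problem

Bioinformatics papers constantly name the databases and software they use —
*UniProt*, *BLAST*, *Gene Ontology* — and constantly introduce new ones.
Recognising these mentions automatically is harder than it looks: resource
names collide with ordinary English words ("analysis" and "Network" are both
published tool names), appear as acronyms or case variants, and a large share
of mentions in any paper refer to the resource that very paper introduces, so
no curated inventory can ever cover them.  `resner` implements the full
pipeline for this task: a dictionary baseline, a feature-based sequence
tagger, a corpus-wide second labelling pass, strict/lenient evaluation,
descriptive analytics of name composition, and rule-based clue detectors for
the mention contexts that carry signal (head terms, enumerations, titles,
versions, citations, comparisons).

## Data model

All user-facing functions exchange tibbles.  A *corpus* is one row per
document (`doc_id`, `title`, `text`, plus a `tokens` list-column); *mentions*
are flat tibbles of character spans (`doc_id`, `start`, `end`, `surface`,
`rtype`, `source`); *labels* are flat per-token `B`/`I`/`O` tibbles.  All
offsets are 0-based and half-open, the convention of standoff annotation
tooling, and every reader validates spans against the text on load.

The tokeniser treats maximal alphanumeric runs as tokens and every other
visible character as its own token, with two domain extensions: decimal /
version strings (`1.83`, `v1.10`) and — on by default — database record
identifiers (`GO:0007089`) stay single tokens.  The identifier rule exists
because splitting `GO:0007089` at the colon lets a dictionary entry `GO`
match inside record identifiers, a characteristic false-positive mode of
dictionary matching in this domain; a separate matcher-level suppression
(reject a candidate immediately followed by `:` + digits) guards the same
failure when identifier tokenisation is off.  POS tags and lemmas come from a
deterministic rule-based provider (Penn tag vocabulary); the contract is only
that identical text yields identical annotations, and any external
tagger can be substituted by replacing the `pos`/`lemma` columns.

## Dictionary matching

`match_dictionary()` performs leftmost-longest, non-overlapping matching of
dictionary variants over token-boundary spans.  Case handling is asymmetric
by design: variants of four characters or fewer, and all-caps variants, match
case-sensitively, while longer mixed-case variants also match
case-insensitively.  The asymmetry reflects how ambiguity scales with case
folding — short names and acronyms ("GO", "ACT") collide with ordinary words
as soon as case is ignored, while long names ("Gene Ontology") rarely do.
Variants shared by entries of different types produce `UNSPECIFIED` mentions
rather than a guess.

`detect_abbreviations()` implements Schwartz–Hearst pairing of
"Long Form (SF)" definitions: short-form characters are aligned right-to-left
inside the preceding words, the first short-form character must begin a word,
and candidates without letters (e.g. `(2 %)`) are rejected.  When enabled in
the matcher, short forms whose long form is a dictionary variant become
document-local variants, so an acronym defined once is matched throughout the
document.

## Sequence tagging

The tagger is a linear-chain discriminative model over B-I-O labels: an
averaged structured perceptron with first-order transition weights and
Viterbi decoding.  It consumes exactly the feature set a CRF would: per-token
shape (`MySQL` → `XxXXX`), a four-slot class-presence signature (`Xx__`), six
orthographic flags, the token/lemma/POS lexical group, a dictionary
membership flag, and an optional syntactic-relation feature (sorted,
underscore-joined relation labels; `NONE` when no provider is attached), all
copied across a context window of two tokens back and one forward — the
window that worked best in development.  Sentence shuffling is the only
randomness and is driven by one seed, so training is exactly reproducible;
models persist to a plain-text directory (weights at full precision plus a
JSON sidecar with window, groups, epochs and seed) and reload to
byte-identical tagging.  Averaging was chosen over a single final weight
vector because it removes the last-epoch ordering sensitivity that plain
perceptrons suffer from; eight epochs are enough for the corpus sizes used
here, and the default is recorded in the model artifact.

Decoded label sequences pass through `repair_bio()`, which turns any `I` not
continuing a mention (including across sentence boundaries) into `B`; the
repair is idempotent and applied uniformly so downstream consumers can assume
valid sequences.

## Two-pass post-processing

The motivating failure mode: a model recognises a name once in a document and
misses its other occurrences.  `postprocess_labels()` therefore collects
corpus-wide votes per exact token surface (how often pass 1 labelled it `B`/`I`
versus `O`, over the corpus currently being tagged — transductive by design)
and promotes an `O` token only when three conditions all hold: a strict
majority of its occurrences were labelled ("more often than not", ties
reject); it is in the dictionary or is an acronym of at least two characters
containing no digits; and it is not one of the four blacklisted words
(*analysis*, *genomes*, *cycle*, *cell*) that caused a large share of false
positives when promoted.  Existing labels are never removed, so token-level
recall cannot decrease; adjacent promoted tokens merge into one mention
(first `B`, rest `I`).  Vote keys are case-sensitive surfaces while the
blacklist comparison is case-insensitive — the blacklist is a set of word
forms, not surfaces.  Note the promotion acronym test is deliberately
stricter than the orthographic `isAcronym` feature, which admits digits.

## Evaluation

`compare_mentions()` scores at the mention level in two modes: *strict*
(offsets must match exactly) and *lenient* (any character overlap).  Lenient
pairing is greedy in gold order and one-to-one, so a single long prediction
cannot absorb several gold mentions; this choice keeps lenient counts
comparable with strict ones and makes the dominance property (lenient ≥
strict for every score) provable.  Precision, recall and F are percentages
with the 0/0 → 0 convention.

`cross_validate()` splits at document level (seeded shuffle, round-robin, fold
sizes within one), evaluates the dictionary baseline on held-out folds only,
trains the tagger on the remaining folds and tags the held-out fold with
optional post-processing.  Summaries report min/max/mean of fold scores
(macro) and the pooled micro-average; the two differ exactly when folds are
unbalanced, which the tests pin down on a constructed two-fold fixture
(fold counts (1,0,1) and (3,0,1): mean recall 62.5 %, micro 66.7 %).
`feature_ablation()` reruns the tagger per dropped feature group under a
shared fold assignment with post-processing disabled, so group contributions
are not confounded by the dictionary-aware second pass.  `iaa()` reuses the
evaluator for inter-annotator agreement, reporting both directions because
precision and recall swap when the reference annotator changes.

## Name analytics

`corpus_summary()` aggregates gold mentions (totals, distinct exact surfaces,
per-document means and maxima, singleton surfaces, database share).
`stem_token_frequency()` Porter-stems the tokens of each name and ranks stem
counts; the Porter (1980) algorithm is implemented in the package (including
the later "logi" revision) and verified against the classic example pairs.
`pos_pattern_profile()` counts space-joined POS-tag patterns over unique
(surface, pattern) pairs, so one surface tagged two ways contributes two
patterns.  `variability_stats()` reports unique variants per resource; for
corpus names the grouping of surface forms into resources is supplied as
input, because that grouping is editorial knowledge, not an algorithm.

## Clue detectors

Each detector is a pure function of one sentence (or the title) and emits
clue/candidate spans: head terms (*database*, *software*, *tool*, *program*,
*simulator*, *system*, *library*, *service*) with an adjacent name-shaped
token run; Hearst-style enumerations (`tools: A, B, and C`; `programs such as
A and B`); the new-resource title pattern (`Name: description`, with the
pre-colon part at most four name-shaped tokens and a guard rejecting titles
containing *method*/*algorithm*); version strings (`v1.10`, `version 1.83`,
bare `1.8` suppressed before unit tokens such as GHz); name-shaped tokens
before citation brackets or URLs; and comparison cues (*better than*,
*compared to*, *Like X, Y*).  "Name-shaped" — capitalised, all-caps,
internal-capital or letter-digit tokens, at most four in a run, minus a
stop-word list — is the package's own operationalisation; published analyses
of these contexts give examples rather than definitions.
`clue_cooccurrence()` quantifies how discriminative a candidate clue regex is
(fraction of clue sentences containing a mention, and the reverse).

## Synthetic corpora

`generate_corpus()` builds seeded annotated corpora that reproduce the
*statistical* structure this task cares about — within-document mention
repetition, acronym/long-form variants, ambiguous common-word names placed
both as mentions and as plain text, novel out-of-dictionary names, and
clue-bearing sentence shapes — from templates, without any natural-language
model, so generation is fully deterministic.  Filler deliberately includes
sentences that mirror the mention templates with ordinary noun phrases, and
capitalised ordinary words (*Figure*, *Table*, *DNA*), so neither local word
context nor a proper-noun tag alone separates resource tokens; their
orthography does.  Defaults (about eight mentions per document over
twenty documents, repetition 0.5, novel-name rate 0.25, ambiguity 0.05,
variant rate 0.15, clue-context rate 0.3) were fixed once to echo the profile
of manually annotated corpora in this field at a size where the full test
suite runs in well under a minute; the generator's rates are recovered from
realised corpora within ten percent at sixty documents.

What passing tests on synthetic corpora do **not** show: performance on real
full text.  Real papers have richer discourse, unseen sentence structure,
section layout, tables and references; the synthetic results demonstrate
correctness of the machinery and the *direction* of effects (post-processing
recovers repeated mentions, orthographic features matter when names are
orthographically distinctive, dictionary recall collapses as novel names
rise), not absolute scores.

## Numerical and degenerate-input choices

Scores are kept at full precision internally and rounded only in the
report-style summary view (`summary_view()`, whole percentages).  Zero
denominators yield zero scores.  Empty documents tokenise to empty token
tables and tag to empty label lists; empty dictionaries match nothing;
regexes matching no sentence co-occur with flag `no_match` rather than `NaN`
fractions.  Mentions that do not align with token boundaries are snapped
outward with a warning rather than dropped, preserving recall accounting.
Tie-breaks are deterministic everywhere (alphabetical for ranked stems and
patterns, first-candidate for lenient pairing).

## Known limitations

The built-in POS provider derives proper-noun tags largely from
capitalisation, so lexical features partially proxy orthographic ones; the
ablation machinery accepts externally supplied tags when a cleaner separation
is needed.  No dependency parser is bundled: syntactic features default to
the `NONE` sentinel unless a relations provider is attached.  Typed
evaluation (database vs software) is carried on mentions but not scored by
default.  Clue detectors emit candidates, not decisions; combining them into
a voting classifier is deliberately out of scope.
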