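test_that("normalise_words trims, lowercases, fuses and corrects", {
  expect_equal(normalise_words("  Peaceful "), "peaceful")
  expect_equal(normalise_words("pain-free"), "painfree")
  expect_equal(normalise_words("at peace"), "atpeace")
  expect_equal(normalise_words(c("", "   ", NA)), c("", "", ""))
  expect_equal(normalise_words("'sad.'"), "sad")
  expect_equal(normalise_words("peacefull",
                               c(peacefull = "peaceful")), "peaceful")
})

test_that("the cascade resolves stages in strict order with provenance", {
  lex <- cascade_lexicon()
  res <- match_words(
    c("sad", "dying", "relational", "unafraid", "after", ""),
    lex, alias_map = c(unafraid = "fear")
  )
  expect_equal(as.character(res$provenance),
               c("ORIGINAL", "LEMMA", "STEM", "MANUAL", "MISSING", "BLANK"))
  expect_equal(res$matched_word,
               c("sad", "die", "relat", "fear", NA, NA))
  # LEMMA inherits the base form's scores downstream
  expect_equal(vad_lookup(lex, "die")$valence, 1.67)
})

test_that("a verbatim lexicon word never falls through to later stages", {
  lex <- cascade_lexicon()
  # alias tries to hijack "sad"; the exact match must win
  res <- match_words("sad", lex, alias_map = c(sad = "peace"))
  expect_equal(as.character(res$provenance), "ORIGINAL")
  expect_equal(res$matched_word, "sad")
  for (w in lex$word) {
    r <- match_words(w, lex)
    expect_equal(as.character(r$provenance), "ORIGINAL")
  }
})

test_that("matching is idempotent: matched words re-match as ORIGINAL", {
  lex <- cascade_lexicon()
  first <- match_words(c("dying", "relational", "scared"), lex)
  expect_true(all(!is.na(first$matched_word)))
  again <- match_words(first$matched_word, lex)
  expect_true(all(as.character(again$provenance) == "ORIGINAL"))
})

test_that("identity transformers confine provenance to non-inflected classes", {
  lex <- cascade_lexicon()
  res <- match_words(c("sad", "dying", "unafraid", "", "zzz"), lex,
                     alias_map = c(unafraid = "fear"),
                     lemmatiser = identity_transformer,
                     stemmer = identity_transformer)
  expect_true(all(as.character(res$provenance) %in%
                    c("ORIGINAL", "MANUAL", "MISSING", "BLANK")))
})

test_that("alias maps only move mass from MISSING to MANUAL", {
  lex <- cascade_lexicon()
  words <- c("sad", "dying", "relational", "unafraid", "qqq", "")
  without <- match_ledger(match_words(words, lex))
  with <- match_ledger(match_words(words, lex,
                                   alias_map = c(unafraid = "fear")))
  cnt <- function(l, p) l$count[l$provenance == p]
  for (p in c("ORIGINAL", "LEMMA", "STEM", "BLANK")) {
    expect_equal(cnt(with, p), cnt(without, p))
  }
  expect_equal(cnt(with, "MANUAL"), cnt(without, "MANUAL") + 1L)
  expect_equal(cnt(with, "MISSING"), cnt(without, "MISSING") - 1L)
})

test_that("alias targets missing from the lexicon warn and stay MISSING", {
  lex <- demo_lexicon()
  expect_warning(
    res <- match_words("qqq", lex, alias_map = c(qqq = "notaword")),
    "absent from lexicon"
  )
  expect_equal(as.character(res$provenance), "MISSING")
})

test_that("match_table partitions every slot and conserves totals", {
  lex <- cascade_lexicon()
  resp <- make_responses(list(
    r1 = list(self_t1 = c("sad", "", "zzz")),
    r2 = list(self_t1 = c("peace", "fear", "death")),
    r3 = list(self_t1 = c("dying", "relational", "natural")),
    r4 = list(self_t1 = c("die", "scary", "inevitable"))
  ))
  mt <- match_table(resp, lex)
  expect_equal(sum(mt$ledger$count), nrow(resp))
  expect_equal(sum(mt$ledger$pct), 100)
  cnt <- function(p) mt$ledger$count[mt$ledger$provenance == p]
  expect_equal(cnt("ORIGINAL"), 8L)
  expect_equal(cnt("LEMMA"), 1L)
  expect_equal(cnt("STEM"), 1L)
  expect_equal(cnt("BLANK"), 1L)
  expect_equal(cnt("MISSING"), 1L)
  # scores travel with the match
  sad_row <- mt$matches[mt$matches$word == "sad", ]
  expect_equal(sad_row$valence, 2.10)
})

test_that("match_table validates its input shape", {
  lex <- demo_lexicon()
  expect_error(match_table(tibble::tibble(a = 1), lex), "missing columns")
  bad_slot <- tibble::tibble(respondent_id = 1, activity = "self_t1",
                             slot = 4, word = "sad")
  expect_error(match_table(bad_slot, lex), "slot index")
  bad_act <- tibble::tibble(respondent_id = 1, activity = "week9",
                            slot = 1, word = "sad")
  expect_error(match_table(bad_act, lex), "unknown activity")
})

test_that("word maps load from two-column files with comments", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# comment", "", "peacefull,peaceful",
               "unafraid,fear"), path)
  map <- read_word_map(path)
  expect_equal(unname(map["peacefull"]), "peaceful")
  expect_equal(length(map), 2)

  shipped <- read_word_map(system.file("extdata", "example_alias_map.csv",
                                       package = "vadsent"))
  expect_true("unafraid" %in% names(shipped))

  writeLines("onlyonefield", path)
  expect_error(read_word_map(path), "two fields")
})

test_that("the spelling map applies before the cascade", {
  lex <- demo_lexicon()
  res <- match_words("peacefull", lex,
                     spelling_map = c(peacefull = "peaceful"))
  expect_equal(as.character(res$provenance), "ORIGINAL")
  expect_equal(res$matched_word, "peaceful")
})
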