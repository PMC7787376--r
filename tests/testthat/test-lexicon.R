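test_that("read_lexicon loads the shipped norms fixture with printed values", {
  lex <- read_lexicon(fixture_lexicon_path())
  expect_s3_class(lex, "vad_lexicon")
  expect_equal(nrow(lex), 9)
  hit <- vad_lookup(lex, "death")
  expect_true(hit$matched)
  expect_equal(hit$valence, 1.89)
  expect_equal(vad_lookup(lex, "die")$valence, 1.67)
  pf <- vad_lookup(lex, "peaceful")
  expect_equal(c(pf$valence, pf$arousal, pf$dominance), c(8.0, 4.38, 6.84))
})

test_that("lexicon loading rejects malformed input", {
  path <- withr::local_tempfile(fileext = ".csv")

  writeLines(c("Word,V.Mean.Sum,A.Mean.Sum,D.Mean.Sum", "calm,9.5,2,5"), path)
  expect_error(read_lexicon(path), "\\[1, 9\\]")

  writeLines(c("Word,V.Mean.Sum,A.Mean.Sum,D.Mean.Sum",
               "Sad,2.1,3.5,3.8", "sad ,2.1,3.5,3.8"), path)
  expect_error(read_lexicon(path), "duplicate")

  writeLines("Word,V.Mean.Sum,A.Mean.Sum,D.Mean.Sum", path)
  expect_error(read_lexicon(path), "empty")

  writeLines(c("Word,Valence", "calm,5"), path)
  expect_error(read_lexicon(path), "lacks column")

  expect_error(read_lexicon("no/such/file.csv"), "not found")
})

test_that("column_map and tab delimiters are honoured", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("token\tv\ta\td", "calm\t7.5\t2.0\t6.0"), path)
  lex <- read_lexicon(path, column_map = c(word = "token", valence = "v",
                                           arousal = "a", dominance = "d"))
  expect_equal(lex$word, "calm")
  expect_equal(lex$valence, 7.5)
})

test_that("reverse_scale is the 10 - x involution with fixed point 5", {
  expect_equal(reverse_scale(1), 9)
  expect_equal(reverse_scale(9), 1)
  expect_equal(reverse_scale(5), 5)
  expect_equal(reverse_scale(4.27), 5.73)
  x <- seq(1, 9, by = 0.13)
  expect_equal(reverse_scale(reverse_scale(x)), x)
  expect_error(reverse_scale(0.5), "\\[1, 9\\]")
  expect_error(reverse_scale(9.01), "\\[1, 9\\]")
})

test_that("orient reverses flagged dimensions and is an involution", {
  lex <- demo_lexicon()
  expect_equal(orient(lex, "intuitive"), lex)

  rev_target <- c(valence = "reversed", arousal = "intuitive",
                  dominance = "intuitive")
  flipped <- orient(lex, rev_target)
  expect_equal(vad_lookup(flipped, "sad")$valence, 7.90)
  expect_equal(vad_lookup(flipped, "sad")$arousal, 3.49)
  expect_equal(lexicon_orientation(flipped)[["valence"]], "reversed")

  back <- orient(flipped, "intuitive")
  expect_equal(as.data.frame(back), as.data.frame(lex))
  expect_equal(nrow(flipped), nrow(lex))
  expect_identical(flipped$word, lex$word)
})

test_that("a reversed-orientation source file lands on the intuitive scale", {
  # raw instrument scale: 1 = happy ... 9 = unhappy; the loader is told so
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Word,V.Mean.Sum,A.Mean.Sum,D.Mean.Sum",
               "grim,7.9,3,4"), path)
  lex <- read_lexicon(path, orientation = c(valence = "reversed",
                                            arousal = "reversed",
                                            dominance = "intuitive"))
  lex <- orient(lex, "intuitive")
  expect_equal(vad_lookup(lex, "grim")$valence, 2.1)
  expect_equal(vad_lookup(lex, "grim")$arousal, 7)
  expect_equal(vad_lookup(lex, "grim")$dominance, 4)
})

test_that("lookup is exact-key only and absence is a value", {
  lex <- demo_lexicon()
  miss <- vad_lookup(lex, "zzz")
  expect_false(miss$matched)
  expect_true(is.na(miss$valence))
  # near-misses do not match
  expect_false(vad_lookup(lex, "peacefull")$matched)
  expect_false(vad_lookup(lex, "Sad")$matched)
})

test_that("summarise_dimension computes n-1 moments and stays ordered", {
  lex <- vad_lexicon(c("a", "b"), valence = c(2, 4), arousal = c(3, 3),
                     dominance = c(1, 9))
  s <- summarise_dimension(lex, "valence")
  expect_equal(s$mean, 3)
  expect_equal(s$sd, sqrt(2))
  expect_equal(s$min, 2)
  expect_equal(s$max, 4)
  expect_equal(s$n_words, 2)

  one <- vad_lexicon("a", 5, 5, 5)
  expect_warning(s1 <- summarise_dimension(one), "degenerate")
  expect_equal(s1$sd, c(0, 0, 0))

  for (seed in 1:5) {
    rl <- random_lexicon(30, seed)
    s <- summarise_dimension(rl)
    expect_true(all(s$min <= s$mean & s$mean <= s$max))
  }
})

test_that("load -> lookup round-trips every source row", {
  lex <- read_lexicon(fixture_lexicon_path())
  src <- read.csv(fixture_lexicon_path())
  got <- vad_lookup(lex, tolower(src$Word))
  expect_true(all(got$matched))
  expect_equal(got$valence, src$V.Mean.Sum)
  expect_equal(got$arousal, src$A.Mean.Sum)
  expect_equal(got$dominance, src$D.Mean.Sum)
})

test_that("norms conformance checker flags agreement and disagreement", {
  # synthetic stand-in file with known statistics
  lex <- vad_lexicon(c("death", "peaceful", "die", "w4"),
                     valence = c(1.89, 8.0, 1.67, 5.0),
                     arousal = c(5.53, 4.38, 6.90, 4.0),
                     dominance = c(3.42, 6.84, 3.29, 5.0))
  expected <- tibble::tribble(
    ~check, ~expected,
    "n_words", 4,
    "valence_mean", mean(c(1.89, 8.0, 1.67, 5.0)),
    "death_valence", 1.89,
    "peaceful_valence", 8.0
  )
  res <- check_norms_conformance(lex, expected)
  expect_true(all(res$pass))

  expected$expected[2] <- 9  # wrong corpus mean must fail
  res2 <- check_norms_conformance(lex, expected)
  expect_false(res2$pass[2])
  expect_true(res2$pass[1])
})
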