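# shared fixtures built in code

fixture_lexicon_path <- function() {
  system.file("extdata", "demo_lexicon.csv", package = "vadsent")
}

# lexicon with extra synthetic base forms so every cascade stage can fire:
# "relat" is reachable only by Porter stemming, "scare" only by the
# dictionary lemmatiser
cascade_lexicon <- function() {
  base <- as.data.frame(demo_lexicon())
  extra <- data.frame(
    word = c("relat", "scare"),
    valence = c(5.0, 3.1),
    arousal = c(4.0, 6.0),
    dominance = c(5.0, 3.5)
  )
  vad_lexicon(c(base$word, extra$word),
              c(base$valence, extra$valence),
              c(base$arousal, extra$arousal),
              c(base$dominance, extra$dominance))
}

# long response table from a named list: list(r1 = list(self_t1 = c(...)))
make_responses <- function(spec) {
  purrr::imap_dfr(spec, function(acts, id) {
    purrr::imap_dfr(acts, function(words, act) {
      stopifnot(length(words) == 3)
      tibble::tibble(respondent_id = id, activity = act,
                     slot = 1:3, word = words)
    })
  })
}

# random small lexicon for property-style loops
random_lexicon <- function(n, seed) {
  set.seed(seed)
  vad_lexicon(
    words = sprintf("rw%03d", seq_len(n)),
    valence = runif(n, 1, 9),
    arousal = runif(n, 1, 9),
    dominance = runif(n, 1, 9)
  )
}

# hand formula oracle for a paired t-test, independent of the package path
oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  md <- sum(d) / n
  sd_d <- sqrt(sum((d - md)^2) / (n - 1))
  se <- sd_d / sqrt(n)
  t <- md / se
  list(mean_diff = md, se = se, t = t, df = n - 1,
       p = 2 * pt(-abs(t), n - 1), d_z = md / sd_d)
}

oracle_welch_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x); v2 <- var(y)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
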