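#' Built-in demonstration lexicon
#'
#' A small VAD lexicon of death-related and filler words with published
#' norm values (intuitive orientation), sufficient to exercise the whole
#' pipeline without the full ~14,000-word norms file. The core entries are
#' the words whose norms are quoted in studies of death-word sentiment
#' (inevitable, sad, fear, scary, peaceful, peace, natural, death, die);
#' `fillers` adds extra synthetic entries spread over the rating space so
#' matching and distribution summaries have something to chew on.
#'
#' @param fillers Number of additional synthetic filler words (default 0).
#' @param seed Seed for the filler ratings (ignored when `fillers = 0`).
#' @return A [vad_lexicon()] in intuitive orientation.
#' @examples
#' vad_lookup(demo_lexicon(), c("death", "peaceful"))
#' @export
demo_lexicon <- function(fillers = 0, seed = 1) {
  core <- tibble::tribble(
    ~word, ~valence, ~arousal, ~dominance,
    "inevitable", 4.10, 4.27, 3.15,
    "sad", 2.10, 3.49, 3.84,
    "fear", 2.93, 6.14, 3.32,
    "scary", 3.00, 5.35, 3.70,
    "peaceful", 8.00, 4.38, 6.84,
    "peace", 7.75, 4.65, 7.17,
    "natural", 6.42, 3.67, 5.16,
    "death", 1.89, 5.53, 3.42,
    "die", 1.67, 6.90, 3.29
  )
  if (fillers > 0) {
    rng <- local_rng(seed)
    fill <- tibble::tibble(
      word = sprintf("filler%03d", seq_len(fillers)),
      valence = rng$runif(fillers, 1.3, 8.5),
      arousal = rng$runif(fillers, 1.6, 7.8),
      dominance = rng$runif(fillers, 1.7, 7.9)
    )
    core <- dplyr::bind_rows(core, fill)
  }
  new_vad_lexicon(core, "intuitive")
}

#' Most-frequent death words by activity
#'
#' The twenty most frequently reported words for each of the three
#' elicitation activities (self at baseline, perceived others at baseline,
#' self at course end) with their occurrence counts and the percentage of
#' that activity's respondents listing them, as published for the study
#' cohort (1,350 baseline respondents; 582 at course end). Used to seed
#' the multinomial word model of the synthetic-cohort generator and as a
#' reference shape for [top_words()].
#'
#' @return A tibble with columns `activity`, `rank`, `word`, `count`, `pct`.
#' @export
reference_word_frequencies <- function() {
  self_t1 <- tibble::tribble(
    ~word, ~count, ~pct,
    "inevitable", 280, 20.7, "sad", 192, 14.2, "peace", 143, 10.6,
    "natural", 135, 10.0, "peaceful", 118, 8.7, "final", 105, 7.8,
    "loss", 103, 7.6, "sadness", 99, 7.3, "unknown", 77, 5.7,
    "release", 70, 5.2, "relief", 63, 4.7, "scared", 52, 3.9,
    "curious", 51, 3.8, "emotional", 51, 3.8, "comfortable", 50, 3.7,
    "grief", 50, 3.7, "fear", 50, 3.7, "normal", 47, 3.5,
    "accepting", 44, 3.3, "scary", 44, 3.3
  )
  other_t1 <- tibble::tribble(
    ~word, ~count, ~pct,
    "fear", 289, 21.4, "sad", 251, 18.6, "scary", 178, 13.2,
    "loss", 173, 12.8, "scared", 153, 11.3, "sadness", 114, 8.4,
    "fearful", 108, 8.0, "grief", 105, 7.8, "unknown", 101, 7.5,
    "denial", 93, 6.9, "taboo", 90, 6.7, "pain", 88, 6.5,
    "inevitable", 87, 6.4, "painful", 81, 6.0, "frightening", 69, 5.1,
    "final", 62, 4.6, "end", 52, 3.9, "lonely", 49, 3.6,
    "frightened", 41, 3.0, "afraid", 39, 2.9
  )
  self_t2 <- tibble::tribble(
    ~word, ~count, ~pct,
    "inevitable", 116, 19.9, "peaceful", 86, 14.9, "peace", 63, 10.8,
    "natural", 51, 8.8, "sad", 46, 7.9, "final", 40, 6.9,
    "comfortable", 37, 6.4, "accepting", 32, 5.5, "acceptance", 30, 5.2,
    "calm", 22, 3.8, "curious", 22, 3.8, "sadness", 22, 3.8,
    "informed", 21, 3.6, "normal", 21, 3.6, "loss", 20, 3.4,
    "love", 20, 3.4, "transition", 20, 3.4, "dignity", 19, 3.3,
    "life", 19, 3.3, "painfree", 18, 3.1
  )
  dplyr::bind_rows(
    dplyr::mutate(self_t1, activity = "self_t1", rank = dplyr::row_number()),
    dplyr::mutate(other_t1, activity = "other_t1", rank = dplyr::row_number()),
    dplyr::mutate(self_t2, activity = "self_t2", rank = dplyr::row_number())
  )[, c("activity", "rank", "word", "count", "pct")]
}

# Seedable RNG scoped to a closure so fixture generation never perturbs the
# caller's random stream.
local_rng <- function(seed) {
  env <- new.env()
  runif_ <- function(n, min = 0, max = 1) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed + get0("calls", envir = env, ifnotfound = 0L))
    assign("calls", get0("calls", envir = env, ifnotfound = 0L) + 1L,
           envir = env)
    stats::runif(n, min, max)
  }
  list(runif = runif_)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
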