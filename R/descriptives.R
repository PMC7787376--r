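#' Most frequent words for an activity
#'
#' Word-occurrence counts (by word, not participant: a respondent listing
#' a word twice contributes two occurrences) over normalised word forms,
#' with the percentage of the activity's respondents who listed the word
#' at least once. Rows are ordered by descending count with an
#' alphabetical tie-break.
#'
#' @param responses Long response table (see [score_activities()]).
#' @param activity One of [vad_activities].
#' @param k Number of rows to return; larger than the vocabulary returns
#'   everything.
#' @param spelling_map Optional curated spelling corrections applied during
#'   normalisation.
#' @param raw_forms If `TRUE`, count raw (trimmed, case-preserved) forms
#'   instead of normalised forms, for audit.
#' @return A tibble with columns `word`, `count`, `pct_participants`.
#' @export
top_words <- function(responses, activity, k = 20, spelling_map = NULL,
                      raw_forms = FALSE) {
  responses <- validate_responses(responses)
  if (!activity %in% vad_activities) {
    stop("unknown activity: ", activity, call. = FALSE)
  }
  act <- responses[responses$activity == activity, ]
  if (raw_forms) {
    act$token <- stringr::str_trim(dplyr::coalesce(act$word, ""))
  } else {
    act$token <- normalise_words(act$word, spelling_map)
  }
  act <- act[act$token != "", ]
  n_resp <- dplyr::n_distinct(act$respondent_id)
  if (nrow(act) == 0) {
    return(tibble::tibble(word = character(0), count = integer(0),
                          pct_participants = numeric(0)))
  }
  counts <- act |>
    dplyr::count(word = .data$token, name = "count")
  by_resp <- act |>
    dplyr::distinct(.data$respondent_id, .data$token) |>
    dplyr::count(word = .data$token, name = "n_respondents")
  counts |>
    dplyr::left_join(by_resp, by = "word") |>
    dplyr::mutate(pct_participants = 100 * .data$n_respondents / n_resp) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$word) |>
    dplyr::select("word", "count", "pct_participants") |>
    utils::head(k)
}

#' Count distinct words used in an activity
#'
#' Distinct normalised words over the activity's non-blank slots; case and
#' spacing variants collapse.
#'
#' @inheritParams top_words
#' @return Integer count.
#' @export
unique_word_count <- function(responses, activity, spelling_map = NULL) {
  responses <- validate_responses(responses)
  if (!activity %in% vad_activities) {
    stop("unknown activity: ", activity, call. = FALSE)
  }
  tokens <- normalise_words(responses$word[responses$activity == activity],
                            spelling_map)
  length(unique(tokens[tokens != ""]))
}

#' Word overlap between two activities
#'
#' For each respondent who answered both activities, the number of shared
#' words between the two triples (set intersection of normalised words,
#' duplicates collapsed), and the aggregate distribution: the percentage
#' of respondents whose word sets were entirely different, who changed at
#' least one word, and who gave identical sets. Overlap compares the words
#' people chose (pre-lexicon-matching), not matched lemmas.
#'
#' @inheritParams top_words
#' @param activity_a,activity_b Two of [vad_activities].
#' @return A list with `per_respondent` (tibble: `respondent_id`,
#'   `n_shared`) and `aggregate` (tibble: `n_respondents`,
#'   `pct_all_different`, `pct_any_different`, `pct_identical`).
#' @export
word_overlap <- function(responses, activity_a, activity_b,
                         spelling_map = NULL) {
  responses <- validate_responses(responses)
  for (a in c(activity_a, activity_b)) {
    if (!a %in% vad_activities) stop("unknown activity: ", a, call. = FALSE)
  }
  sets_for <- function(activity) {
    act <- responses[responses$activity == activity, ]
    act$token <- normalise_words(act$word, spelling_map)
    act <- act[act$token != "", ]
    split(act$token, act$respondent_id)
  }
  sa <- sets_for(activity_a)
  sb <- sets_for(activity_b)
  both <- intersect(names(sa), names(sb))
  per <- tibble::tibble(
    respondent_id = both,
    n_shared = vapply(both, function(id) {
      length(intersect(unique(sa[[id]]), unique(sb[[id]])))
    }, integer(1), USE.NAMES = FALSE),
    identical_set = vapply(both, function(id) {
      setequal(sa[[id]], sb[[id]])
    }, logical(1), USE.NAMES = FALSE)
  )
  n <- nrow(per)
  aggregate <- tibble::tibble(
    n_respondents = n,
    pct_all_different = 100 * sum(per$n_shared == 0) / max(1L, n),
    pct_any_different = 100 * sum(!per$identical_set) / max(1L, n),
    pct_identical = 100 * sum(per$identical_set) / max(1L, n)
  )
  list(per_respondent = per[c("respondent_id", "n_shared")],
       aggregate = aggregate)
}

#' Normalised score histogram
#'
#' Bins scores on one dimension and divides the counts by the series
#' total, so each series sums to 1 and a response word-set can be overlaid
#' against a full lexicon regardless of their very different sizes.
#'
#' @param data A data frame with a column named by `dimension` and
#'   optionally a `series` column distinguishing overlaid groups (a
#'   [vad_lexicon()] works directly).
#' @param dimension One of `"valence"`, `"arousal"`, `"dominance"`.
#' @param breaks Strictly increasing bin edges covering \[1, 9\]
#'   (default: half-unit bins).
#' @return A tibble of class `vad_histogram` with columns `series`,
#'   `bin_lo`, `bin_hi`, `mid`, `count`, `prop`.
#' @export
score_histogram <- function(data, dimension = vad_dimensions,
                            breaks = seq(1, 9, by = 0.5)) {
  dimension <- match.arg(dimension)
  if (is.unsorted(breaks, strictly = TRUE)) {
    stop("breaks must be strictly increasing", call. = FALSE)
  }
  if (breaks[1] > 1 || breaks[length(breaks)] < 9) {
    stop("breaks must cover [1, 9]", call. = FALSE)
  }
  df <- tibble::as_tibble(as.data.frame(data))
  if (!dimension %in% names(df)) {
    stop("data has no ", dimension, " column", call. = FALSE)
  }
  if (!"series" %in% names(df)) df$series <- "all"
  df <- df[!is.na(df[[dimension]]), ]
  x <- df[[dimension]]
  if (any(x < breaks[1] | x > breaks[length(breaks)])) {
    stop("scores outside bin coverage", call. = FALSE)
  }
  out <- df |>
    dplyr::mutate(bin = cut(.data[[dimension]], breaks = breaks,
                            include.lowest = TRUE, right = FALSE,
                            labels = FALSE)) |>
    dplyr::mutate(bin = pmin(.data$bin, length(breaks) - 1L)) |>
    dplyr::count(.data$series, .data$bin, name = "count") |>
    tidyr::complete(series = unique(df$series),
                    bin = seq_len(length(breaks) - 1L),
                    fill = list(count = 0L)) |>
    dplyr::group_by(.data$series) |>
    dplyr::mutate(prop = .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::mutate(bin_lo = breaks[.data$bin],
                  bin_hi = breaks[.data$bin + 1L],
                  mid = (.data$bin_lo + .data$bin_hi) / 2) |>
    dplyr::select("series", "bin_lo", "bin_hi", "mid", "count", "prop")
  class(out) <- c("vad_histogram", class(out))
  attr(out, "dimension") <- dimension
  out
}
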