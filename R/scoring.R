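#' Activity labels
#'
#' The three elicitation activities: three words about one's own feelings
#' at baseline (`self_t1`), three words attributed to others in the
#' general public at baseline (`other_t1`), and three words about one's
#' own feelings at course end (`self_t2`).
#' @format Character vector of length 3.
#' @export
vad_activities <- c("self_t1", "other_t1", "self_t2")

#' Score activities: per-respondent VAD means
#'
#' Matches every word slot against the lexicon and averages the matched
#' words' valence, arousal and dominance within each
#' (respondent, activity). Blank and unmatched slots are excluded from the
#' mean; all three dimensions always use the same contributing word set.
#' Means are undefined (`NA`) when fewer than `min_words` words matched.
#' Duplicate words within a triple are counted as given -- a respondent
#' repeating a word weights it.
#'
#' @param responses Long response table: `respondent_id`, `activity`,
#'   `slot` (1--3), `word`.
#' @param lex A [vad_lexicon()] in intuitive orientation.
#' @param min_words Minimum matched words for a defined score (default 1;
#'   set to 3 for a strict complete-triple rule).
#' @inheritParams match_words
#' @return A tibble with one row per (respondent, activity): `valence`,
#'   `arousal`, `dominance` means and `n_matched` (0--3).
#' @examples
#' resp <- tibble::tibble(
#'   respondent_id = 1, activity = "self_t1", slot = 1:3,
#'   word = c("sad", "fear", "peaceful")
#' )
#' score_activities(resp, demo_lexicon())
#' @export
score_activities <- function(responses, lex,
                             min_words = 1,
                             alias_map = NULL,
                             spelling_map = NULL,
                             lemmatiser = dictionary_lemmatiser(lex),
                             stemmer = porter_stem) {
  mt <- match_table(responses, lex, alias_map = alias_map,
                    spelling_map = spelling_map,
                    lemmatiser = lemmatiser, stemmer = stemmer)
  check_slot_uniqueness(mt$matches)
  scores <- mt$matches |>
    dplyr::group_by(.data$respondent_id, .data$activity) |>
    dplyr::summarise(
      n_matched = sum(!is.na(.data$matched_word)),
      valence = mean(.data$valence, na.rm = TRUE),
      arousal = mean(.data$arousal, na.rm = TRUE),
      dominance = mean(.data$dominance, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(vad_dimensions),
      ~ ifelse(.data$n_matched >= min_words, .x, NA_real_)
    ))
  scores[c("respondent_id", "activity", vad_dimensions, "n_matched")]
}

check_slot_uniqueness <- function(matches) {
  dup <- matches |>
    dplyr::count(.data$respondent_id, .data$activity, .data$slot) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate (respondent, activity, slot) rows in response table",
         call. = FALSE)
  }
  n_per <- matches |>
    dplyr::count(.data$respondent_id, .data$activity)
  if (any(n_per$n != 3)) {
    stop("each (respondent, activity) must have exactly 3 slots",
         call. = FALSE)
  }
  invisible(matches)
}

#' Build the respondent-level analysis table
#'
#' Pivots activity scores wide into the nine analysis variables
#' (3 activities x 3 dimensions, named e.g. `self_t1_valence`) and
#' left-joins demographics. Respondents missing an activity -- typically
#' attrition before the course-end elicitation -- get `NA` scores for it,
#' which is exactly what the imputation layer consumes.
#'
#' @inheritParams score_activities
#' @param demographics A data frame keyed by `respondent_id` with columns
#'   `age`, `female`, `australia`, `health_professional`, `university`
#'   (numeric age; the rest 0/1 or logical). Extra columns are carried
#'   through; a missing demographics table (`NULL`) yields scores only.
#' @return A tibble with one row per respondent: `respondent_id`, nine
#'   score columns, and demographics.
#' @export
build_analysis_table <- function(responses, demographics = NULL, lex,
                                 min_words = 1,
                                 alias_map = NULL,
                                 spelling_map = NULL,
                                 lemmatiser = dictionary_lemmatiser(lex),
                                 stemmer = porter_stem) {
  scores <- score_activities(responses, lex, min_words = min_words,
                             alias_map = alias_map,
                             spelling_map = spelling_map,
                             lemmatiser = lemmatiser, stemmer = stemmer)
  wide <- scores |>
    dplyr::select(-"n_matched") |>
    tidyr::pivot_longer(dplyr::all_of(vad_dimensions),
                        names_to = "dimension", values_to = "score") |>
    dplyr::mutate(variable = paste(.data$activity, .data$dimension,
                                   sep = "_")) |>
    dplyr::select("respondent_id", "variable", "score") |>
    tidyr::pivot_wider(names_from = "variable", values_from = "score")
  # stable column order: all nine variables, absent activities filled NA
  all_vars <- as.vector(outer(vad_activities, vad_dimensions, paste,
                              sep = "_"))
  for (v in setdiff(all_vars, names(wide))) wide[[v]] <- NA_real_
  wide <- wide[c("respondent_id", all_vars)]
  if (!is.null(demographics)) {
    demographics <- tibble::as_tibble(demographics)
    if (!"respondent_id" %in% names(demographics)) {
      stop("demographics must have a respondent_id column", call. = FALSE)
    }
    if (anyDuplicated(demographics$respondent_id)) {
      stop("duplicate respondent_id in demographics", call. = FALSE)
    }
    wide <- dplyr::left_join(wide, demographics, by = "respondent_id")
  }
  wide
}

#' Names of the nine analysis variables
#' @return Character vector `self_t1_valence` ... `self_t2_dominance`.
#' @export
analysis_score_columns <- function() {
  as.vector(outer(vad_activities, vad_dimensions, paste, sep = "_"))
}

#' Read a long response table from a delimited file
#'
#' Expects columns `respondent_id`, `activity`, `slot`, `word` (extra
#' columns are dropped); comma- or tab-delimited, UTF-8.
#'
#' @param path File path.
#' @param delim Field delimiter (`NULL` autodetects).
#' @return A validated long response tibble.
#' @export
read_responses <- function(path, delim = NULL) {
  if (is.null(delim)) {
    first <- readLines(path, n = 1L, warn = FALSE)
    delim <- if (length(first) && grepl("\t", first)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(word = readr::col_character(),
                                                   .default = readr::col_guess()))
  validate_responses(raw)[c("respondent_id", "activity", "slot", "word")]
}

#' Import a wide three-columns-per-activity response layout
#'
#' Survey exports commonly store one row per respondent with three word
#' columns per activity. This importer reshapes such a file into the long
#' layout used everywhere else, driven by an explicit column mapping (the
#' wide schema is never guessed).
#'
#' @param data A data frame, or a path to a delimited file.
#' @param column_map Named list mapping each activity label (see
#'   [vad_activities]) to its three word-column names, plus an `id` entry
#'   naming the respondent-id column.
#' @param delim Delimiter when `data` is a path (`NULL` autodetects).
#' @return A long response tibble (`respondent_id`, `activity`, `slot`,
#'   `word`).
#' @export
import_wide_responses <- function(data, column_map, delim = NULL) {
  if (is.character(data) && length(data) == 1) {
    if (is.null(delim)) {
      first <- readLines(data, n = 1L, warn = FALSE)
      delim <- if (length(first) && grepl("\t", first)) "\t" else ","
    }
    data <- readr::read_delim(data, delim = delim, show_col_types = FALSE,
                              progress = FALSE)
  }
  data <- tibble::as_tibble(data)
  if (is.null(column_map$id)) stop("column_map needs an 'id' entry",
                                   call. = FALSE)
  acts <- intersect(vad_activities, names(column_map))
  if (length(acts) == 0) stop("column_map names no known activity",
                              call. = FALSE)
  purrr::map_dfr(acts, function(act) {
    cols <- column_map[[act]]
    if (length(cols) != 3) {
      stop("activity ", act, " must map to exactly 3 columns", call. = FALSE)
    }
    absent <- setdiff(cols, names(data))
    if (length(absent) > 0) {
      stop("wide table lacks column(s): ", paste(absent, collapse = ", "),
           call. = FALSE)
    }
    tibble::tibble(
      respondent_id = rep(data[[column_map$id]], 3),
      activity = act,
      slot = rep(1:3, each = nrow(data)),
      word = as.character(unlist(data[cols], use.names = FALSE))
    )
  }) |>
    dplyr::arrange(.data$respondent_id, .data$activity, .data$slot)
}
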