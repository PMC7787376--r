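#' Normalise raw response words
#'
#' Trims whitespace, lowercases, strips surrounding punctuation, collapses
#' internal spaces and hyphens (so `"pain-free"` becomes `"painfree"`, the
#' fused form seen in survey word lists), then applies a curated spelling
#' map if the token is one of its keys. There is deliberately no automatic
#' spell-checker: corrections are an explicit, reviewable map so the
#' pipeline stays reproducible.
#'
#' @param x Character vector of raw response strings.
#' @param spelling_map Named character vector (`misspelling = replacement`)
#'   or `NULL`.
#' @return Character vector of normalised tokens (`""` for blank input).
#' @examples
#' normalise_words(c("  Peaceful ", "pain-free", ""))
#' @export
normalise_words <- function(x, spelling_map = NULL) {
  out <- stringr::str_trim(as.character(x))
  out[is.na(out)] <- ""
  out <- tolower(out)
  # surrounding punctuation only; interior apostrophes etc. survive
  out <- stringr::str_replace_all(out, "^[[:punct:]]+|[[:punct:]]+$", "")
  out <- stringr::str_replace_all(out, "[\\s-]+", "")
  if (!is.null(spelling_map)) {
    hit <- out %in% names(spelling_map)
    out[hit] <- unname(spelling_map[out[hit]])
  }
  out
}

#' Dictionary-based lemmatiser over a lexicon
#'
#' Builds a single-token lemmatiser that maps common English inflected
#' forms back to base forms present in the lexicon: plural `-s`/`-es`/
#' `-ies`, progressive `-ing` (with consonant doubling and dropped-`e`
#' recovery, and `-ying` from `-ie` verbs), and past `-ed`. A variant is
#' only mapped when the recovered base form is itself a lexicon word, which
#' is what makes the lemmatiser dictionary-based rather than rule-guessing.
#' Tokens with no applicable mapping are returned unchanged.
#'
#' @param lex A [vad_lexicon()] serving as the dictionary of base forms.
#' @return A function `character(1) -> character(1)` suitable for
#'   [match_words()].
#' @examples
#' lemma <- dictionary_lemmatiser(demo_lexicon())
#' lemma("dying")  # "die"
#' @export
dictionary_lemmatiser <- function(lex) {
  stopifnot(inherits(lex, "vad_lexicon"))
  words <- lex$word
  force(words)
  function(token) {
    if (is.na(token) || token == "" || token %in% words) return(token)
    for (cand in lemma_candidates(token)) {
      if (cand %in% words) return(cand)
    }
    token
  }
}

# candidate base forms for an inflected token, most specific first
lemma_candidates <- function(token) {
  n <- nchar(token)
  cands <- character(0)
  add <- function(x) cands <<- c(cands, x)
  if (endsWith(token, "ies") && n > 4) add(paste0(substr(token, 1, n - 3), "y"))
  if (endsWith(token, "ying") && n > 4) add(paste0(substr(token, 1, n - 4), "ie"))
  if (endsWith(token, "ing") && n > 4) {
    stem <- substr(token, 1, n - 3)
    add(paste0(stem, "e"))           # hoping -> hope
    add(stem)                        # singing -> sing... (falling -> fall)
    if (nchar(stem) > 2 &&
        substr(stem, nchar(stem), nchar(stem)) ==
        substr(stem, nchar(stem) - 1, nchar(stem) - 1)) {
      add(substr(stem, 1, nchar(stem) - 1))   # hopping -> hop
    }
  }
  if (endsWith(token, "ied") && n > 4) add(paste0(substr(token, 1, n - 3), "y"))
  if (endsWith(token, "ed") && n > 3) {
    stem <- substr(token, 1, n - 2)
    add(paste0(stem, "e"))           # scared -> scare
    add(stem)                        # feared -> fear
    if (nchar(stem) > 2 &&
        substr(stem, nchar(stem), nchar(stem)) ==
        substr(stem, nchar(stem) - 1, nchar(stem) - 1)) {
      add(substr(stem, 1, nchar(stem) - 1))   # stopped -> stop
    }
  }
  if (endsWith(token, "es") && n > 3) add(substr(token, 1, n - 2))
  if (endsWith(token, "s") && n > 2 && !endsWith(token, "ss")) {
    add(substr(token, 1, n - 1))
  }
  unique(cands)
}

#' Identity token transformer
#'
#' A lemmatiser/stemmer that returns its input unchanged; useful for
#' isolating cascade stages in tests and audits.
#' @param token A single token.
#' @return `token`.
#' @export
identity_transformer <- function(token) token

match_provenances <- c("ORIGINAL", "LEMMA", "STEM", "MANUAL",
                       "MISSING", "BLANK")

#' Resolve response words against a lexicon via the fallback cascade
#'
#' Each raw word is normalised, then resolved by the first stage that
#' succeeds, in this strict order: (1) exact lexicon lookup of the
#' normalised token (`ORIGINAL`); (2) lookup of its lemma (`LEMMA`);
#' (3) lookup of its Porter stem (`STEM`); (4) a curated alias map entry
#' (`MANUAL`, mirroring hand-curation after automated failure); otherwise
#' `MISSING`. Blank input short-circuits to `BLANK`. Later stages are never
#' consulted after a success, and the cascade never overrides an earlier
#' stage.
#'
#' Alias targets absent from the lexicon trigger a lint warning and the
#' word falls through to `MISSING`; choosing safe aliases (a word with an
#' ambiguous base form should *not* be aliased) is the curator's
#' responsibility.
#'
#' @param raw Character vector of raw response words.
#' @param lex A [vad_lexicon()], already oriented.
#' @param alias_map,spelling_map Named character vectors (or `NULL`).
#' @param lemmatiser,stemmer Single-token transformer functions.
#' @return A tibble with columns `raw`, `normalised`, `matched_word`
#'   (`NA` when unmatched) and `provenance`.
#' @examples
#' match_words(c("sad", "dying", "zzz", ""), demo_lexicon())
#' @export
match_words <- function(raw, lex,
                        alias_map = NULL,
                        spelling_map = NULL,
                        lemmatiser = dictionary_lemmatiser(lex),
                        stemmer = porter_stem) {
  stopifnot(inherits(lex, "vad_lexicon"))
  if (!is.null(alias_map)) {
    bad <- setdiff(unname(alias_map), lex$word)
    if (length(bad) > 0) {
      warning("alias map targets absent from lexicon (ignored): ",
              paste(unique(bad), collapse = ", "), call. = FALSE)
    }
  }
  raw <- as.character(raw)
  norm <- normalise_words(raw, spelling_map)
  matched <- rep(NA_character_, length(raw))
  prov <- rep("MISSING", length(raw))

  blank <- norm == ""
  prov[blank] <- "BLANK"

  hit <- !blank & in_lexicon(lex, norm)
  matched[hit] <- norm[hit]
  prov[hit] <- "ORIGINAL"

  todo <- which(!blank & !hit)
  for (i in todo) {
    lemma <- lemmatiser(norm[i])
    if (!is.na(lemma) && lemma %in% lex$word) {
      matched[i] <- lemma; prov[i] <- "LEMMA"; next
    }
    stem <- stemmer(norm[i])
    if (!is.na(stem) && stem %in% lex$word) {
      matched[i] <- stem; prov[i] <- "STEM"; next
    }
    if (!is.null(alias_map) && norm[i] %in% names(alias_map)) {
      target <- unname(alias_map[[norm[i]]])
      if (target %in% lex$word) {
        matched[i] <- target; prov[i] <- "MANUAL"
      }
    }
  }
  tibble::tibble(
    raw = raw,
    normalised = norm,
    matched_word = matched,
    provenance = factor(prov, levels = match_provenances)
  )
}

#' Match a long response table and account for every slot
#'
#' Applies [match_words()] to a long word-slot table and returns both the
#' per-slot match results (with the lexicon's VAD scores joined on) and a
#' provenance ledger partitioning every slot into exactly one class.
#'
#' @param responses A data frame with columns `respondent_id`, `activity`,
#'   `slot` (1--3) and `word`.
#' @param lex A [vad_lexicon()].
#' @inheritParams match_words
#' @return A list with elements `matches` (tibble: the response columns
#'   plus `normalised`, `matched_word`, `provenance`, `valence`, `arousal`,
#'   `dominance`) and `ledger` (see [match_ledger()]).
#' @export
match_table <- function(responses, lex,
                        alias_map = NULL,
                        spelling_map = NULL,
                        lemmatiser = dictionary_lemmatiser(lex),
                        stemmer = porter_stem) {
  responses <- validate_responses(responses)
  mm <- match_words(responses$word, lex,
                    alias_map = alias_map, spelling_map = spelling_map,
                    lemmatiser = lemmatiser, stemmer = stemmer)
  scores <- vad_lookup(lex, mm$matched_word)
  matches <- dplyr::bind_cols(
    responses[c("respondent_id", "activity", "slot", "word")],
    mm[c("normalised", "matched_word", "provenance")],
    scores[c("valence", "arousal", "dominance")]
  )
  list(matches = matches, ledger = match_ledger(matches))
}

#' Provenance ledger of a match table
#'
#' Counts and percentages of word slots per provenance class. Counts sum
#' to the number of slots processed; every slot lands in exactly one class.
#'
#' @param matches A tibble with a `provenance` column, as produced by
#'   [match_words()] or [match_table()].
#' @return A tibble with columns `provenance`, `count`, `pct`.
#' @export
match_ledger <- function(matches) {
  prov <- factor(as.character(matches$provenance), levels = match_provenances)
  counts <- table(prov)
  tibble::tibble(
    provenance = factor(names(counts), levels = match_provenances),
    count = as.integer(counts),
    pct = 100 * as.integer(counts) / max(1L, length(prov))
  )
}

validate_responses <- function(responses) {
  needed <- c("respondent_id", "activity", "slot", "word")
  missing_cols <- setdiff(needed, names(responses))
  if (length(missing_cols) > 0) {
    stop("response table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  responses <- tibble::as_tibble(responses)
  if (any(!responses$slot %in% 1:3)) {
    stop("slot index must be 1, 2 or 3", call. = FALSE)
  }
  bad_act <- setdiff(unique(responses$activity), vad_activities)
  if (length(bad_act) > 0) {
    stop("unknown activity label(s): ", paste(bad_act, collapse = ", "),
         "; expected ", paste(vad_activities, collapse = ", "),
         call. = FALSE)
  }
  responses$word <- as.character(responses$word)
  responses
}

#' Read a two-column word map (alias or spelling corrections)
#'
#' Reads a delimited two-column UTF-8 file of `raw -> replacement` pairs.
#' Lines whose first non-blank character is `#` are comments.
#'
#' @param path File path; comma- or tab-delimited, no header by default.
#' @param delim Field delimiter (`NULL` autodetects tab vs comma).
#' @return Named character vector (`raw = replacement`).
#' @export
read_word_map <- function(path, delim = NULL) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) return(stats::setNames(character(0), character(0)))
  if (is.null(delim)) delim <- if (grepl("\t", lines[1])) "\t" else ","
  parts <- stringr::str_split_fixed(lines, stringr::fixed(delim), 2)
  if (any(parts[, 2] == "")) {
    stop("word map lines must have two fields: raw", delim, "replacement",
         call. = FALSE)
  }
  stats::setNames(stringr::str_trim(parts[, 2]),
                  tolower(stringr::str_trim(parts[, 1])))
}
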