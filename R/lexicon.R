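#' VAD lexicons
#'
#' A VAD lexicon is a tibble of words with crowd-rated valence, arousal and
#' dominance means on the 1--9 scale, in the format popularised by the
#' Warriner et al. English word norms. Each dimension carries an explicit
#' orientation flag: `"intuitive"` means higher = happier / more aroused /
#' more in-control; `"reversed"` means the opposite. Orientation is never
#' inferred from the data -- rating-collection instruments differ in which
#' endpoint is labelled "happy", and a silent guess would flip the sign of
#' every downstream comparison.
#'
#' @param words Character vector of words. Lowercased and trimmed on
#'   construction; duplicates after normalisation are an error.
#' @param valence,arousal,dominance Numeric ratings in \[1, 9\].
#' @param orientation Named character vector giving the orientation of each
#'   dimension, e.g. `c(valence = "intuitive", arousal = "intuitive",
#'   dominance = "intuitive")`. A single unnamed value is recycled to all
#'   three dimensions.
#' @return A `vad_lexicon`: a tibble with columns `word`, `valence`,
#'   `arousal`, `dominance` and an `orientation` attribute.
#' @examples
#' lex <- vad_lexicon(
#'   words = c("calm", "panic"),
#'   valence = c(7.8, 2.2), arousal = c(2.0, 7.9), dominance = c(6.5, 3.1),
#'   orientation = "intuitive"
#' )
#' vad_lookup(lex, "calm")
#' @export
vad_lexicon <- function(words, valence, arousal, dominance,
                        orientation = "intuitive") {
  df <- tibble::tibble(
    word = as.character(words),
    valence = as.numeric(valence),
    arousal = as.numeric(arousal),
    dominance = as.numeric(dominance)
  )
  new_vad_lexicon(df, normalise_orientation(orientation))
}

vad_dimensions <- c("valence", "arousal", "dominance")

normalise_orientation <- function(orientation) {
  ok <- c("intuitive", "reversed")
  if (length(orientation) == 1 && is.null(names(orientation))) {
    orientation <- stats::setNames(rep(orientation, 3), vad_dimensions)
  }
  if (!all(vad_dimensions %in% names(orientation))) {
    stop("`orientation` must name all of valence, arousal, dominance ",
         "(or be a single unnamed value)", call. = FALSE)
  }
  orientation <- orientation[vad_dimensions]
  if (!all(orientation %in% ok)) {
    stop("orientation flags must be 'intuitive' or 'reversed'", call. = FALSE)
  }
  orientation
}

# validating constructor: word normalisation, uniqueness, rating bounds
new_vad_lexicon <- function(df, orientation) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(c("word", vad_dimensions), names(df))
  if (length(missing_cols) > 0) {
    stop("lexicon is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) stop("lexicon is empty", call. = FALSE)
  df$word <- stringr::str_trim(tolower(df$word))
  if (any(df$word == "" | is.na(df$word))) {
    stop("lexicon contains empty or NA words", call. = FALSE)
  }
  dup <- unique(df$word[duplicated(df$word)])
  if (length(dup) > 0) {
    stop("duplicate lexicon words after lowercasing/trimming: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  for (dim in vad_dimensions) {
    x <- df[[dim]]
    if (any(is.na(x))) stop("NA ", dim, " rating in lexicon", call. = FALSE)
    if (any(x < 1 | x > 9)) {
      stop(dim, " ratings must lie in [1, 9]; offending word(s): ",
           paste(utils::head(df$word[x < 1 | x > 9], 5), collapse = ", "),
           call. = FALSE)
    }
  }
  out <- tibble::as_tibble(df[c("word", vad_dimensions)])
  attr(out, "orientation") <- normalise_orientation(orientation)
  class(out) <- c("vad_lexicon", class(out))
  out
}

#' @export
print.vad_lexicon <- function(x, ...) {
  ori <- lexicon_orientation(x)
  cat("<vad_lexicon> ", nrow(x), " words; orientation: ",
      paste(names(ori), ori, sep = "=", collapse = ", "), "\n", sep = "")
  NextMethod()
}

#' Orientation flags of a lexicon
#'
#' @param lex A [vad_lexicon()].
#' @return Named character vector over valence, arousal, dominance with
#'   values `"intuitive"` or `"reversed"`.
#' @export
lexicon_orientation <- function(lex) {
  stopifnot(inherits(lex, "vad_lexicon"))
  attr(lex, "orientation")
}

#' Read a VAD lexicon from a delimited file
#'
#' Reads word norms from a comma- or tab-delimited UTF-8 file. Column names
#' default to the published Warriner norms header; any file with a word
#' column and three numeric mean-rating columns can be mapped via
#' `column_map`. Words are lowercased and trimmed; duplicates after
#' normalisation, out-of-range ratings, missing columns and empty files are
#' all hard errors -- lexicon integrity underlies every downstream number.
#'
#' @param path Path to the delimited file.
#' @param column_map Named character vector mapping the internal names
#'   `word`, `valence`, `arousal`, `dominance` to column names in the file.
#' @param orientation Orientation of the ratings *in the file* (see
#'   [vad_lexicon()]). This must be stated explicitly: published norms
#'   files are commonly already on the intuitive low-to-high scale, while
#'   raw rating instruments may run 1 = happy to 9 = unhappy.
#' @param delim Field delimiter; `NULL` (default) chooses tab when the
#'   first line contains one, comma otherwise.
#' @return A [vad_lexicon()].
#' @export
read_lexicon <- function(path,
                         column_map = c(word = "Word",
                                        valence = "V.Mean.Sum",
                                        arousal = "A.Mean.Sum",
                                        dominance = "D.Mean.Sum"),
                         orientation = "intuitive",
                         delim = NULL) {
  if (!file.exists(path)) stop("lexicon file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    first <- readLines(path, n = 1L, warn = FALSE)
    delim <- if (length(first) && grepl("\t", first)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (nrow(raw) == 0) stop("lexicon file is empty: ", path, call. = FALSE)
  needed <- c("word", vad_dimensions)
  if (!all(needed %in% names(column_map))) {
    stop("column_map must name word, valence, arousal, dominance",
         call. = FALSE)
  }
  absent <- setdiff(unname(column_map[needed]), names(raw))
  if (length(absent) > 0) {
    stop("lexicon file lacks column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  df <- tibble::tibble(
    word = as.character(raw[[column_map[["word"]]]]),
    valence = as.numeric(raw[[column_map[["valence"]]]]),
    arousal = as.numeric(raw[[column_map[["arousal"]]]]),
    dominance = as.numeric(raw[[column_map[["dominance"]]]])
  )
  new_vad_lexicon(df, orientation)
}

#' Reverse a 1--9 rating scale
#'
#' The unique affine involution of \[1, 9\] that swaps the endpoints:
#' `10 - x`. Used to move ratings between the raw instrument orientation
#' (e.g. 1 = happy ... 9 = unhappy) and the intuitive low-to-high scale.
#'
#' @param x Numeric vector of ratings in \[1, 9\].
#' @return `10 - x`.
#' @examples
#' reverse_scale(c(1, 5, 9))  # 9 5 1
#' @export
reverse_scale <- function(x) {
  if (any(!is.na(x) & (x < 1 | x > 9))) {
    stop("ratings must lie in [1, 9]", call. = FALSE)
  }
  10 - x
}

#' Re-orient a lexicon
#'
#' Maps each dimension whose orientation flag differs from `target` through
#' [reverse_scale()] and updates the flags. Applying `orient()` twice with
#' swapped targets is the identity.
#'
#' @param lex A [vad_lexicon()].
#' @param target Target orientation (see [vad_lexicon()]); defaults to
#'   intuitive on all three dimensions, the canonical in-memory orientation.
#' @return A [vad_lexicon()] in the target orientation.
#' @export
orient <- function(lex, target = "intuitive") {
  stopifnot(inherits(lex, "vad_lexicon"))
  target <- normalise_orientation(target)
  current <- lexicon_orientation(lex)
  df <- tibble::as_tibble(unclass(lex)[c("word", vad_dimensions)])
  for (dim in vad_dimensions) {
    if (current[[dim]] != target[[dim]]) df[[dim]] <- reverse_scale(df[[dim]])
  }
  new_vad_lexicon(df, target)
}

#' Exact lexicon lookup
#'
#' Exact-key retrieval only, never fuzzy: absence is a value, not an error.
#' Fallback resolution of unmatched words is the matching cascade's job
#' ([match_words()]), not the lexicon's.
#'
#' @param lex A [vad_lexicon()].
#' @param words Character vector of normalised (lowercase, trimmed) tokens.
#' @return A tibble with one row per input word: `word`, `matched` (logical)
#'   and the three ratings (`NA` where absent).
#' @export
vad_lookup <- function(lex, words) {
  stopifnot(inherits(lex, "vad_lexicon"))
  idx <- match(words, lex$word)
  tibble::tibble(
    word = as.character(words),
    matched = !is.na(idx),
    valence = lex$valence[idx],
    arousal = lex$arousal[idx],
    dominance = lex$dominance[idx]
  )
}

in_lexicon <- function(lex, words) words %in% lex$word

#' Summarise a lexicon's score distributions
#'
#' Mean, standard deviation (n - 1 denominator), minimum and maximum of the
#' ratings on each dimension. A single-entry lexicon has no dispersion; its
#' sd is reported as 0 with a degeneracy warning so summaries stay total.
#'
#' @param lex A [vad_lexicon()].
#' @param dimensions Dimensions to summarise (default all three).
#' @return A tibble with columns `dimension`, `n_words`, `mean`, `sd`,
#'   `min`, `max`.
#' @export
summarise_dimension <- function(lex, dimensions = vad_dimensions) {
  stopifnot(inherits(lex, "vad_lexicon"))
  dimensions <- match.arg(dimensions, vad_dimensions, several.ok = TRUE)
  if (nrow(lex) == 1) {
    warning("single-entry lexicon: sd reported as 0 (degenerate)",
            call. = FALSE)
  }
  purrr::map_dfr(dimensions, function(dim) {
    x <- lex[[dim]]
    tibble::tibble(
      dimension = dim,
      n_words = length(x),
      mean = mean(x),
      sd = if (length(x) > 1) stats::sd(x) else 0,
      min = min(x),
      max = max(x)
    )
  })
}

#' Check a full norms file against published corpus statistics
#'
#' Convenience audit for users holding the complete Warriner et al. norms
#' file (13,915 words): verifies the corpus-level statistics reported for
#' it (dimension means and ranges, word count) and a set of spot-check
#' entries. Returns a tibble of checks rather than failing, so the caller
#' decides what counts as conformance.
#'
#' @param lex A [vad_lexicon()] loaded from the candidate file, already in
#'   intuitive orientation.
#' @param expected A tibble with columns `check`, `expected` as produced by
#'   [warriner_reference_statistics()] (the default).
#' @param tol Absolute tolerance for mean comparisons (default 0.005, i.e.
#'   agreement at the printed precision).
#' @return The `expected` tibble with `observed` and `pass` columns added.
#' @export
check_norms_conformance <- function(lex,
                                    expected = warriner_reference_statistics(),
                                    tol = 0.005) {
  stopifnot(inherits(lex, "vad_lexicon"))
  summ <- summarise_dimension(lex)
  value_of <- function(check) {
    switch(check,
      n_words = nrow(lex),
      valence_mean = summ$mean[summ$dimension == "valence"],
      arousal_mean = summ$mean[summ$dimension == "arousal"],
      dominance_mean = summ$mean[summ$dimension == "dominance"],
      valence_min = summ$min[summ$dimension == "valence"],
      valence_max = summ$max[summ$dimension == "valence"],
      arousal_min = summ$min[summ$dimension == "arousal"],
      arousal_max = summ$max[summ$dimension == "arousal"],
      dominance_min = summ$min[summ$dimension == "dominance"],
      dominance_max = summ$max[summ$dimension == "dominance"],
      {
        # "<word>_<dimension>" spot checks
        parts <- strsplit(check, "_", fixed = TRUE)[[1]]
        dim <- parts[length(parts)]
        w <- paste(parts[-length(parts)], collapse = "_")
        vad_lookup(lex, w)[[dim]]
      }
    )
  }
  expected$observed <- vapply(expected$check, value_of, numeric(1))
  expected$pass <- !is.na(expected$observed) &
    abs(expected$observed - expected$expected) <= ifelse(
      expected$check == "n_words", 0.5, tol)
  expected
}

#' Published corpus statistics for the Warriner et al. norms
#'
#' The corpus-level statistics and spot-check entries reported for the full
#' 13,915-word norms (intuitive orientation), for use with
#' [check_norms_conformance()].
#'
#' @return A tibble with columns `check`, `expected`.
#' @export
warriner_reference_statistics <- function() {
  tibble::tribble(
    ~check, ~expected,
    "n_words", 13915,
    "valence_mean", 5.06,
    "arousal_mean", 4.21,
    "dominance_mean", 5.18,
    "valence_min", 1.26,
    "valence_max", 8.53,
    "arousal_min", 1.60,
    "arousal_max", 7.79,
    "dominance_min", 1.68,
    "dominance_max", 7.90,
    "death_valence", 1.89,
    "peaceful_valence", 8.0,
    "die_valence", 1.67
  )
}
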