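# Porter (1980) suffix-stripping stemmer. Works on single lowercase ASCII
# tokens; words of length <= 2 are returned unchanged, as in the original
# algorithm. The stemmer is the default third stage of the matching cascade.

#' Porter stem of a word
#'
#' The classic Porter suffix-stripping algorithm. Stems are not guaranteed
#' to be dictionary words (e.g. `"ponies"` stems to `"poni"`); in the
#' matching cascade a stem only matters when it happens to hit a lexicon
#' entry.
#'
#' @param words Character vector of lowercase tokens.
#' @return Character vector of stems.
#' @examples
#' porter_stem(c("singing", "relational", "hopping"))
#' @export
porter_stem <- function(words) {
  vapply(as.character(words), porter_stem1, character(1), USE.NAMES = FALSE)
}

porter_stem1 <- function(w) {
  if (is.na(w) || nchar(w) <= 2 || grepl("[^a-z]", w)) return(w)
  w <- p_step1a(w)
  w <- p_step1b(w)
  w <- p_step1c(w)
  w <- p_step2(w)
  w <- p_step3(w)
  w <- p_step4(w)
  w <- p_step5a(w)
  p_step5b(w)
}

p_chars <- function(w) strsplit(w, "", fixed = TRUE)[[1]]

# consonant at position i: not a vowel, and y counts as a vowel when the
# preceding letter is a consonant
p_is_cons <- function(ch, i) {
  c <- ch[i]
  if (c %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (c == "y") {
    if (i == 1) return(TRUE)
    return(!p_is_cons(ch, i - 1))
  }
  TRUE
}

# measure m: number of vowel-consonant sequences in the stem
p_measure <- function(w) {
  if (nchar(w) == 0) return(0L)
  ch <- p_chars(w)
  cons <- vapply(seq_along(ch), function(i) p_is_cons(ch, i), logical(1))
  m <- 0L
  prev_vowel <- FALSE
  for (i in seq_along(cons)) {
    if (cons[i] && prev_vowel) m <- m + 1L
    prev_vowel <- !cons[i]
  }
  m
}

p_has_vowel <- function(w) {
  if (nchar(w) == 0) return(FALSE)
  ch <- p_chars(w)
  any(!vapply(seq_along(ch), function(i) p_is_cons(ch, i), logical(1)))
}

p_double_cons <- function(w) {
  n <- nchar(w)
  if (n < 2) return(FALSE)
  ch <- p_chars(w)
  ch[n] == ch[n - 1] && p_is_cons(ch, n)
}

# *o condition: stem ends consonant-vowel-consonant, final consonant not w/x/y
p_cvc <- function(w) {
  n <- nchar(w)
  if (n < 3) return(FALSE)
  ch <- p_chars(w)
  p_is_cons(ch, n - 2) && !p_is_cons(ch, n - 1) && p_is_cons(ch, n) &&
    !(ch[n] %in% c("w", "x", "y"))
}

p_ends <- function(w, suffix) {
  n <- nchar(w); s <- nchar(suffix)
  n >= s && substring(w, n - s + 1, n) == suffix
}

p_trim <- function(w, suffix) substring(w, 1, nchar(w) - nchar(suffix))

p_step1a <- function(w) {
  if (p_ends(w, "sses")) return(p_trim(w, "es"))
  if (p_ends(w, "ies")) return(p_trim(w, "es"))
  if (p_ends(w, "ss")) return(w)
  if (p_ends(w, "s")) return(p_trim(w, "s"))
  w
}

p_step1b <- function(w) {
  if (p_ends(w, "eed")) {
    stem <- p_trim(w, "eed")
    if (p_measure(stem) > 0) return(p_trim(w, "d"))
    return(w)
  }
  cleanup <- FALSE
  if (p_ends(w, "ed") && p_has_vowel(p_trim(w, "ed"))) {
    w <- p_trim(w, "ed"); cleanup <- TRUE
  } else if (p_ends(w, "ing") && p_has_vowel(p_trim(w, "ing"))) {
    w <- p_trim(w, "ing"); cleanup <- TRUE
  }
  if (cleanup) {
    if (p_ends(w, "at") || p_ends(w, "bl") || p_ends(w, "iz")) {
      w <- paste0(w, "e")
    } else if (p_double_cons(w) &&
               !p_ends(w, "l") && !p_ends(w, "s") && !p_ends(w, "z")) {
      w <- substring(w, 1, nchar(w) - 1)
    } else if (p_measure(w) == 1 && p_cvc(w)) {
      w <- paste0(w, "e")
    }
  }
  w
}

p_step1c <- function(w) {
  if (p_ends(w, "y") && p_has_vowel(p_trim(w, "y"))) {
    return(paste0(p_trim(w, "y"), "i"))
  }
  w
}

p_sub_if <- function(w, rules, min_m) {
  for (k in seq_len(nrow(rules))) {
    suf <- rules$from[k]
    if (p_ends(w, suf)) {
      stem <- p_trim(w, suf)
      if (p_measure(stem) > min_m - 1) return(paste0(stem, rules$to[k]))
      return(w)  # longest matching suffix decides, even if condition fails
    }
  }
  w
}

p_step2 <- function(w) {
  rules <- data.frame(
    from = c("ational", "tional", "enci", "anci", "izer", "abli", "alli",
             "entli", "eli", "ousli", "ization", "ation", "ator", "alism",
             "iveness", "fulness", "ousness", "aliti", "iviti", "biliti"),
    to = c("ate", "tion", "ence", "ance", "ize", "able", "al",
           "ent", "e", "ous", "ize", "ate", "ate", "al",
           "ive", "ful", "ous", "al", "ive", "ble"),
    stringsAsFactors = FALSE
  )
  # longest-suffix-first ordering
  rules <- rules[order(-nchar(rules$from)), ]
  p_sub_if(w, rules, min_m = 1)
}

p_step3 <- function(w) {
  rules <- data.frame(
    from = c("icate", "ative", "alize", "iciti", "ical", "ful", "ness"),
    to = c("ic", "", "al", "ic", "ic", "", ""),
    stringsAsFactors = FALSE
  )
  rules <- rules[order(-nchar(rules$from)), ]
  p_sub_if(w, rules, min_m = 1)
}

p_step4 <- function(w) {
  sufs <- c("ement", "ance", "ence", "able", "ible", "ment", "ant", "ent",
            "ion", "ism", "ate", "iti", "ous", "ive", "ize", "al", "er",
            "ic", "ou")
  sufs <- sufs[order(-nchar(sufs))]
  for (suf in sufs) {
    if (p_ends(w, suf)) {
      stem <- p_trim(w, suf)
      if (suf == "ion" && !(p_ends(stem, "s") || p_ends(stem, "t"))) return(w)
      if (p_measure(stem) > 1) return(stem)
      return(w)
    }
  }
  w
}

p_step5a <- function(w) {
  if (p_ends(w, "e")) {
    stem <- p_trim(w, "e")
    m <- p_measure(stem)
    if (m > 1 || (m == 1 && !p_cvc(stem))) return(stem)
  }
  w
}

p_step5b <- function(w) {
  if (p_measure(w) > 1 && p_double_cons(w) && p_ends(w, "l")) {
    return(substring(w, 1, nchar(w) - 1))
  }
  w
}
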