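#' Specify a synthetic cohort
#'
#' A generative description of a three-words study cohort: demographic
#' marginals, a per-activity word model, attrition before the course-end
#' activity, and a missing-slot rate. Two word models are supported:
#'
#' * `"latent"`: each (respondent, activity) draws a latent VAD point from
#'   a trivariate normal with the activity's mean vector and a diagonal
#'   covariance; the three words are then drawn from the lexicon with
#'   probability decaying in squared VAD distance from the latent point
#'   (Gaussian kernel of width `kernel_width`). This gives continuous,
#'   tunable effect sizes and is the default for recovery tests.
#' * `"multinomial"`: words are drawn independently from an explicit
#'   per-activity probability table, e.g. one seeded from a published
#'   frequency table.
#'
#' @param n Number of baseline respondents (>= 1).
#' @param age_mean,age_sd,age_range Age marginal (truncated normal).
#' @param p_female,p_australia,p_health_professional,p_university
#'   Bernoulli probabilities of the binary demographics.
#' @param word_model `"latent"` or `"multinomial"`.
#' @param latent_means Named list over [vad_activities], each a length-3
#'   numeric `c(valence, arousal, dominance)` latent mean.
#' @param latent_sds Length-3 numeric: marginal latent SDs per dimension.
#' @param latent_trait_cor Share of the latent variance carried by a
#'   stable respondent trait common to all of that respondent's
#'   activities (default 0.4). This is what makes baseline scores
#'   predictive of course-end scores, as repeated-measures designs
#'   assume; 0 gives independent activities.
#' @param kernel_width Gaussian kernel width (rating units) for
#'   latent-to-word sampling.
#' @param word_probs For the multinomial model: named list over
#'   activities, each a data frame with columns `word`, `prob`
#'   (probabilities are renormalised to sum to 1).
#' @param attrition Probability a baseline respondent is absent at the
#'   course-end activity.
#' @param attrition_mechanism `"mcar"` or `"mar_age"` (log-odds of
#'   dropout decreasing in age, so older respondents are retained more).
#' @param missing_slot_rate Probability any individual word slot is blank.
#' @param age_effect Optional linear dependence of the course-end latent
#'   valence/dominance gain on centred age (rating units per year; 0 off).
#'   Negative values emulate younger respondents changing more.
#' @return An object of class `vad_cohort_spec` (a validated list).
#' @export
cohort_spec <- function(n,
                        age_mean = 49.5, age_sd = 12, age_range = c(18, 84),
                        p_female = 0.937, p_australia = 0.877,
                        p_health_professional = 0.711, p_university = 0.685,
                        word_model = c("latent", "multinomial"),
                        latent_means = NULL,
                        latent_sds = c(1.3, 0.6, 0.95),
                        latent_trait_cor = 0.4,
                        kernel_width = 0.6,
                        word_probs = NULL,
                        attrition = 0.57,
                        attrition_mechanism = c("mcar", "mar_age"),
                        missing_slot_rate = 0.01,
                        age_effect = 0) {
  word_model <- match.arg(word_model)
  attrition_mechanism <- match.arg(attrition_mechanism)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  for (p in c(p_female, p_australia, p_health_professional, p_university,
              attrition, missing_slot_rate)) {
    if (p < 0 || p > 1) stop("probabilities/rates must lie in [0, 1]",
                             call. = FALSE)
  }
  if (word_model == "latent") {
    if (is.null(latent_means)) {
      stop("latent word model needs latent_means", call. = FALSE)
    }
    if (!all(vad_activities %in% names(latent_means))) {
      stop("latent_means must name all activities", call. = FALSE)
    }
    if (any(vapply(latent_means, length, integer(1)) != 3)) {
      stop("each latent mean must have 3 components (V, A, D)",
           call. = FALSE)
    }
    if (length(latent_sds) != 3 || any(latent_sds <= 0)) {
      stop("latent_sds must be 3 positive numbers", call. = FALSE)
    }
    if (latent_trait_cor < 0 || latent_trait_cor >= 1) {
      stop("latent_trait_cor must lie in [0, 1)", call. = FALSE)
    }
  } else {
    if (is.null(word_probs) || !all(vad_activities %in% names(word_probs))) {
      stop("multinomial word model needs word_probs for every activity",
           call. = FALSE)
    }
    word_probs <- lapply(word_probs, function(tab) {
      tab <- tibble::as_tibble(tab)
      if (!all(c("word", "prob") %in% names(tab)) || any(tab$prob < 0) ||
          sum(tab$prob) <= 0) {
        stop("word_probs tables need columns word, prob (prob >= 0)",
             call. = FALSE)
      }
      tab$prob <- tab$prob / sum(tab$prob)
      tab
    })
  }
  structure(list(
    n = as.integer(n),
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    p_female = p_female, p_australia = p_australia,
    p_health_professional = p_health_professional,
    p_university = p_university,
    word_model = word_model,
    latent_means = latent_means, latent_sds = latent_sds,
    latent_trait_cor = latent_trait_cor,
    kernel_width = kernel_width,
    word_probs = word_probs,
    attrition = attrition, attrition_mechanism = attrition_mechanism,
    missing_slot_rate = missing_slot_rate,
    age_effect = age_effect
  ), class = "vad_cohort_spec")
}

#' Default cohort specification mirroring the study conditions
#'
#' A latent-model [cohort_spec()] whose demographic marginals and
#' per-activity latent VAD means are transcribed from the published
#' cohort description: 1,350 baseline respondents; age 49.5 (SD 12,
#' range 18--84); 93.7% female, 87.7% Australia-resident, 71.1% health
#' professionals, 68.5% university-educated; activity VAD means
#' self-baseline (5.25, 4.33, 5.16), others-baseline (3.56, 4.82, 4.12),
#' self course-end (5.90, 4.19, 5.63); 57% attrition before the
#' course-end activity.
#'
#' @param n Cohort size (default 1350).
#' @param ... Overrides forwarded to [cohort_spec()].
#' @return A `vad_cohort_spec`.
#' @export
default_cohort_spec <- function(n = 1350, ...) {
  args <- list(
    n = n,
    latent_means = list(
      self_t1 = c(5.25, 4.33, 5.16),
      other_t1 = c(3.56, 4.82, 4.12),
      self_t2 = c(5.90, 4.19, 5.63)
    ),
    attrition = 0.57
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(cohort_spec, args)
}

#' Dense synthetic vocabulary lexicon
#'
#' A regular lattice of synthetic words over the VAD rating box, used as
#' the sampling vocabulary of the latent word model: with a lattice much
#' finer than the kernel width and spanning the whole rating box (so the
#' kernel support is never clipped near the latent distribution),
#' kernel-weighted word draws are (near-)unbiased for the latent point.
#'
#' @param spacing Lattice spacing in rating units (default 0.5).
#' @param lower,upper Length-3 box corners on (valence, arousal,
#'   dominance); the default spans the full 1--9 scale.
#' @return A [vad_lexicon()] of synthetic `w0001`-style words.
#' @export
lattice_lexicon <- function(spacing = 0.5,
                            lower = c(1, 1, 1),
                            upper = c(9, 9, 9)) {
  grid <- expand.grid(
    valence = seq(lower[1], upper[1], by = spacing),
    arousal = seq(lower[2], upper[2], by = spacing),
    dominance = seq(lower[3], upper[3], by = spacing)
  )
  grid$word <- sprintf("w%04d", seq_len(nrow(grid)))
  new_vad_lexicon(grid[c("word", vad_dimensions)], "intuitive")
}

#' Generate a synthetic cohort
#'
#' Draws demographics, word responses and attrition from a
#' [cohort_spec()], reproducibly from `seed`. The returned truth record
#' stores the generating parameters so recovery tests can compare
#' pipeline output against them.
#'
#' @param spec A [cohort_spec()].
#' @param lex Sampling vocabulary for the latent model (a
#'   [vad_lexicon()]; default [lattice_lexicon()]). Ignored by the
#'   multinomial model. Vocabulary words must carry ratings in the
#'   lexicon used later for scoring if the pipeline is to be closed
#'   end-to-end -- the simplest choice is to score against the same
#'   lexicon.
#' @param seed Integer seed (required).
#' @return A list with `responses` (long tibble), `demographics`
#'   (tibble) and `truth` (list of generating parameters).
#' @export
generate_cohort <- function(spec, lex = lattice_lexicon(), seed) {
  stopifnot(inherits(spec, "vad_cohort_spec"))
  if (missing(seed) || is.null(seed)) {
    stop("generate_cohort() requires an explicit seed", call. = FALSE)
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  n <- spec$n
  ids <- sprintf("r%05d", seq_len(n))

  age <- truncnorm_draw(n, spec$age_mean, spec$age_sd, spec$age_range)
  # stable per-respondent affect trait shared across activities
  trait <- if (spec$word_model == "latent") {
    matrix(stats::rnorm(3 * n), ncol = 3) *
      rep(sqrt(spec$latent_trait_cor) * spec$latent_sds, each = n)
  } else NULL
  demographics <- tibble::tibble(
    respondent_id = ids,
    age = age,
    female = stats::rbinom(n, 1, spec$p_female),
    australia = stats::rbinom(n, 1, spec$p_australia),
    health_professional = stats::rbinom(n, 1, spec$p_health_professional),
    university = stats::rbinom(n, 1, spec$p_university)
  )

  retained <- if (spec$attrition_mechanism == "mcar") {
    stats::rbinom(n, 1, 1 - spec$attrition) == 1
  } else {
    # MAR on age: dropout log-odds decrease with age, calibrated so the
    # marginal dropout rate equals the configured attrition
    z <- scale(age)[, 1]
    eta <- stats::qlogis(spec$attrition) - 0.5 * z
    stats::runif(n) > stats::plogis(eta)
  }

  words_for <- function(activity, who) {
    k <- length(who)
    if (k == 0) return(NULL)
    if (spec$word_model == "latent") {
      mu <- spec$latent_means[[activity]]
      within_sd <- sqrt(1 - spec$latent_trait_cor) * spec$latent_sds
      latent <- matrix(stats::rnorm(3 * k), ncol = 3) *
        rep(within_sd, each = k) +
        trait[who, , drop = FALSE] +
        rep(mu, each = k)
      if (activity == "self_t2" && spec$age_effect != 0) {
        adj <- spec$age_effect * (age[who] - mean(age))
        latent[, 1] <- latent[, 1] + adj  # valence
        latent[, 3] <- latent[, 3] + adj  # dominance
      }
      vocab <- as.matrix(as.data.frame(lex)[vad_dimensions])
      draw_kernel_words(latent, vocab, lex$word, spec$kernel_width)
    } else {
      tab <- spec$word_probs[[activity]]
      matrix(sample(tab$word, 3 * k, replace = TRUE, prob = tab$prob),
             ncol = 3)
    }
  }

  build_rows <- function(activity, who) {
    w <- words_for(activity, who)
    if (is.null(w)) return(NULL)
    blank <- matrix(stats::runif(length(w)) < spec$missing_slot_rate,
                    ncol = 3)
    w[blank] <- ""
    tibble::tibble(
      respondent_id = rep(ids[who], 3),
      activity = activity,
      slot = rep(1:3, each = length(who)),
      word = as.vector(w)
    )
  }

  responses <- dplyr::bind_rows(
    build_rows("self_t1", seq_len(n)),
    build_rows("other_t1", seq_len(n)),
    build_rows("self_t2", which(retained))
  ) |>
    dplyr::arrange(.data$respondent_id, .data$activity, .data$slot)

  list(
    responses = responses,
    demographics = demographics,
    truth = list(spec = spec, seed = seed,
                 retained = stats::setNames(retained, ids))
  )
}

# sample 3 words per latent row with Gaussian-kernel weights over the
# vocabulary; chunked so the weight matrix stays modest
draw_kernel_words <- function(latent, vocab, vocab_words, h) {
  k <- nrow(latent)
  out <- matrix("", nrow = k, ncol = 3)
  chunk <- max(1L, floor(2e6 / nrow(vocab)))
  for (start in seq(1, k, by = chunk)) {
    idx <- start:min(k, start + chunk - 1)
    # squared distances: |v|^2 - 2 v.z + |z|^2 (last term constant per row)
    d2 <- outer(rep(1, length(idx)), rowSums(vocab^2)) -
      2 * latent[idx, , drop = FALSE] %*% t(vocab)
    w <- exp(-(d2 - apply(d2, 1, min)) / (2 * h^2))
    for (j in seq_along(idx)) {
      out[idx[j], ] <- sample(vocab_words, 3, replace = TRUE, prob = w[j, ])
    }
  }
  out
}

truncnorm_draw <- function(n, mean, sd, range) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  out[seq_len(n)]
}

#' Word-probability tables from a published frequency table
#'
#' Turns occurrence counts (e.g. a top-20 table) into per-activity
#' multinomial probabilities for [cohort_spec()]'s multinomial word
#' model. Counts are renormalised within activity; the tail of
#' unlisted words is represented by `n_other` synthetic filler words
#' sharing the residual mass implied by `total_words`.
#'
#' @param freq A tibble like [reference_word_frequencies()]: `activity`,
#'   `word`, `count`.
#' @param total_words Named vector of total word occurrences per activity
#'   (default: the published activity totals).
#' @param n_other Number of filler words carrying the residual mass
#'   (default 50).
#' @return Named list of `word`/`prob` tibbles over activities.
#' @export
word_probs_from_frequencies <- function(freq,
                                        total_words = c(self_t1 = 4259,
                                                        other_t1 = 4128,
                                                        self_t2 = 1859),
                                        n_other = 50) {
  acts <- unique(freq$activity)
  stats::setNames(lapply(acts, function(act) {
    tab <- freq[freq$activity == act, c("word", "count")]
    total <- if (act %in% names(total_words)) total_words[[act]] else
      sum(tab$count)
    resid <- max(0, total - sum(tab$count))
    out <- tibble::tibble(word = tab$word, prob = tab$count / total)
    if (resid > 0 && n_other > 0) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        word = sprintf("other%03d", seq_len(n_other)),
        prob = resid / total / n_other
      ))
    }
    out
  }), acts)
}
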