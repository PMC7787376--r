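#' End-to-end scoring pipeline
#'
#' Runs the full measurement side in one call: match every word slot
#' through the cascade, build the nine-variable analysis table joined
#' with demographics, and return the provenance ledger alongside.
#'
#' @inheritParams build_analysis_table
#' @return A list with `analysis` (the respondent-level analysis table),
#'   `matches` (per-slot match results with scores) and `ledger`
#'   (provenance counts; totals equal the number of word slots).
#' @export
score_pipeline <- function(responses, demographics = NULL, lex,
                           min_words = 1,
                           alias_map = NULL, spelling_map = NULL,
                           lemmatiser = dictionary_lemmatiser(lex),
                           stemmer = porter_stem) {
  mt <- match_table(responses, lex, alias_map = alias_map,
                    spelling_map = spelling_map,
                    lemmatiser = lemmatiser, stemmer = stemmer)
  analysis <- build_analysis_table(responses, demographics, lex,
                                   min_words = min_words,
                                   alias_map = alias_map,
                                   spelling_map = spelling_map,
                                   lemmatiser = lemmatiser,
                                   stemmer = stemmer)
  list(analysis = analysis, matches = mt$matches, ledger = mt$ledger)
}

default_comparisons <- tibble::tibble(
  comparison = c("self_vs_other", "pre_vs_post"),
  a = c("self_t1", "self_t1"),
  b = c("other_t1", "self_t2")
)

#' Paired comparisons of activity sentiment scores
#'
#' The two headline within-subject contrasts -- self versus perceived
#' others at baseline, and self pre versus post course -- on each VAD
#' dimension, as paired t-tests with d_z effect sizes and
#' Bonferroni-flagged significance at `alpha / k` (full precision; the
#' truncated display is cosmetic). In `"mi"` mode the mean difference is
#' estimated within each completed dataset and pooled by Rubin's rules;
#' the per-imputation d_z values are averaged for description (an effect
#' size has no within-imputation SE to pool).
#'
#' @param analysis Analysis table from [build_analysis_table()] (used in
#'   `"complete"` mode, and to define `df_com` in `"mi"` mode).
#' @param mode `"complete"` (complete-case / listwise) or `"mi"`.
#' @param mids A `vad_mids` from [impute_fcs()], required for `"mi"`.
#' @param comparisons Tibble with columns `comparison`, `a`, `b` naming
#'   activity pairs (default: the two headline contrasts).
#' @param alpha,k Family-wise level and number of comparisons for the
#'   Bonferroni flag (defaults .05 and 3, one test per dimension).
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble with one row per comparison x dimension: means,
#'   `estimate` (a - b), `se`, CI, `statistic`, `df`, `p.value`,
#'   `cohen_d`, `n`, `significant`.
#' @export
compare_activities <- function(analysis, mode = c("complete", "mi"),
                               mids = NULL,
                               comparisons = default_comparisons,
                               alpha = 0.05, k = 3, conf_level = 0.95) {
  mode <- match.arg(mode)
  threshold <- bonferroni_alpha(alpha, k)
  grid <- tidyr::expand_grid(comparisons, dimension = vad_dimensions)
  if (mode == "mi" && is.null(mids)) {
    stop("mi mode needs a vad_mids object", call. = FALSE)
  }
  out <- purrr::pmap_dfr(grid, function(comparison, a, b, dimension) {
    ca <- paste(a, dimension, sep = "_")
    cb <- paste(b, dimension, sep = "_")
    if (mode == "complete") {
      tt <- paired_t(analysis[[ca]], analysis[[cb]],
                     conf_level = conf_level)
      tibble::tibble(
        comparison = comparison, dimension = dimension,
        n = tt$n_pairs, mean_a = tt$mean_x, mean_b = tt$mean_y,
        estimate = tt$estimate, se = tt$se,
        conf.low = tt$conf.low, conf.high = tt$conf.high,
        statistic = tt$statistic, df = as.numeric(tt$df),
        p.value = tt$p.value, cohen_d = tt$cohen_d
      )
    } else {
      per <- purrr::map(mids$imputations, function(dat) {
        tt <- paired_t(dat[[ca]], dat[[cb]], conf_level = conf_level)
        list(est = tt$estimate, se = tt$se, d = tt$cohen_d,
             ma = tt$mean_x, mb = tt$mean_y, n = tt$n_pairs)
      })
      pooled <- pool_estimates(
        vapply(per, `[[`, numeric(1), "est"),
        vapply(per, `[[`, numeric(1), "se"),
        df_com = per[[1]]$n - 1, conf_level = conf_level
      )
      tibble::tibble(
        comparison = comparison, dimension = dimension,
        n = per[[1]]$n,
        mean_a = mean(vapply(per, `[[`, numeric(1), "ma")),
        mean_b = mean(vapply(per, `[[`, numeric(1), "mb")),
        estimate = pooled$estimate, se = pooled$se,
        conf.low = pooled$conf.low, conf.high = pooled$conf.high,
        statistic = pooled$statistic, df = pooled$df,
        p.value = pooled$p.value,
        cohen_d = mean(vapply(per, `[[`, numeric(1), "d"))
      )
    }
  })
  out$significant <- !is.na(out$p.value) & out$p.value < threshold
  attr(out, "alpha") <- threshold
  out
}

#' Activity-by-dimension mean matrix for radar plotting
#'
#' The 3 x 3 matrix of mean sentiment scores (activities by dimensions)
#' in long tibble form, the data behind the standard radar comparison of
#' self-baseline, others-baseline and self course-end profiles.
#'
#' @param analysis Analysis table from [build_analysis_table()].
#' @return A tibble with columns `activity`, `dimension`, `mean`, `n`.
#' @export
radar_data <- function(analysis) {
  grid <- tidyr::expand_grid(activity = vad_activities,
                             dimension = vad_dimensions)
  purrr::pmap_dfr(grid, function(activity, dimension) {
    col <- paste(activity, dimension, sep = "_")
    x <- analysis[[col]]
    tibble::tibble(activity = activity, dimension = dimension,
                   mean = mean(x, na.rm = TRUE), n = sum(!is.na(x)))
  })
}

#' Socio-demographic change models for each sentiment dimension
#'
#' For each VAD dimension, a two-block hierarchical regression of the
#' course-end score on its baseline score (block 1) plus age, residency,
#' health-professional status and university education (block 2) -- the
#' standard adjusted-change formulation. In `"mi"` mode coefficients are
#' pooled by Rubin's rules and the non-poolable fit statistics
#' (R-squared, F, their increments) are reported as across-imputation
#' ranges.
#'
#' @inheritParams compare_activities
#' @param block2 Demographic predictors (default age + the three binary
#'   indicators).
#' @return A list with `coefficients` (tibble over `outcome` x `model` x
#'   `term`) and `fit` (tibble of fit statistics: values in `"complete"`
#'   mode, min/max ranges in `"mi"` mode).
#' @export
model_change <- function(analysis, mode = c("complete", "mi"), mids = NULL,
                         block2 = c("age", "australia",
                                    "health_professional", "university"),
                         conf_level = 0.95) {
  mode <- match.arg(mode)
  if (mode == "mi" && is.null(mids)) {
    stop("mi mode needs a vad_mids object", call. = FALSE)
  }
  res <- purrr::map(vad_dimensions, function(dim) {
    outcome <- paste("self_t2", dim, sep = "_")
    block1 <- paste("self_t1", dim, sep = "_")
    if (mode == "complete") {
      fit <- hier_regression(analysis, outcome, block1, block2,
                             conf_level = conf_level)
      coefs <- dplyr::mutate(fit$coefficients, outcome = outcome)
      fitstats <- fit$blocks |>
        tidyr::pivot_longer(-"block", names_to = "statistic",
                            values_to = "value") |>
        dplyr::filter(!is.na(.data$value)) |>
        dplyr::mutate(outcome = outcome)
    } else {
      df_com <- NULL
      coefs <- pooled_analysis(mids, function(dat) {
        fit <- hier_regression(dat, outcome, block1, block2,
                               conf_level = conf_level)
        dplyr::transmute(
          dplyr::filter(fit$coefficients, .data$model == "final"),
          term = .data$term, estimate = .data$estimate, se = .data$se,
          df_com = fit$n - length(block2) - 2
        )
      }, conf_level = conf_level) |>
        dplyr::mutate(model = "final", outcome = outcome)
      # pooled semipartials: average across imputations (descriptive)
      sp <- purrr::map(mids$imputations, function(dat) {
        fit <- hier_regression(dat, outcome, block1, block2,
                               conf_level = conf_level)
        f <- dplyr::filter(fit$coefficients, .data$model == "final")
        stats::setNames(f$semipartial, f$term)
      })
      sp_mean <- Reduce(`+`, sp) / length(sp)
      coefs$semipartial <- unname(sp_mean[coefs$term])
      stat_of <- function(what) {
        fit_stat_range(mids, function(dat) {
          fit <- hier_regression(dat, outcome, block1, block2)
          switch(what,
                 r2_initial = fit$blocks$r.squared[1],
                 r2_final = fit$blocks$r.squared[2],
                 f_initial = fit$blocks$statistic[1],
                 f_final = fit$blocks$statistic[2],
                 delta_r2 = fit$blocks$delta_r2[2],
                 delta_f = fit$blocks$delta_f[2])
        }, name = what)
      }
      fitstats <- purrr::map_dfr(
        c("r2_initial", "f_initial", "r2_final", "f_final",
          "delta_r2", "delta_f"), stat_of) |>
        dplyr::mutate(outcome = outcome)
    }
    list(coefficients = coefs, fit = fitstats)
  })
  list(
    coefficients = purrr::map_dfr(res, "coefficients"),
    fit = purrr::map_dfr(res, "fit")
  )
}
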