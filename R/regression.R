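#' Two-block hierarchical linear regression
#'
#' Ordinary least squares in two blocks: block 1 alone, then block 1 plus
#' block 2, with the increment in explained variance tested by the
#' standard nested-model F
#' \eqn{\Delta F = (\Delta R^2 / q) / ((1 - R^2_{full}) / (n - p - 1))}.
#' Each final-model predictor also gets its semipartial correlation, the
#' signed square root of the R-squared drop when that predictor alone is
#' removed from the full model (sign taken from its coefficient). The
#' canonical use is predicting a course-end sentiment score from its
#' baseline score (block 1) plus socio-demographics (block 2), so that
#' block 2 speaks to change over time.
#'
#' @param data A data frame with complete rows for the listed variables
#'   (rows with any missing value among them are dropped; under multiple
#'   imputation call this per completed copy via [pooled_analysis()]).
#' @param outcome Name of the outcome column.
#' @param block1,block2 Character vectors of predictor column names;
#'   `block2` may be empty.
#' @param conf_level Confidence level for coefficient CIs (default 0.95).
#' @return An object of class `vad_hierreg` with elements `blocks`
#'   (per-block fit: `r.squared`, `statistic`, `df1`, `df2`, `p.value`,
#'   and for block 2 `delta_r2`, `delta_f`, `delta_p`), `coefficients`
#'   (tibble over both models: `model`, `term`, `estimate`, `se`,
#'   `conf.low`, `conf.high`, `p.value`, `semipartial`) and `n`.
#' @export
hier_regression <- function(data, outcome, block1, block2 = character(0),
                            conf_level = 0.95) {
  vars <- c(outcome, block1, block2)
  absent <- setdiff(vars, names(data))
  if (length(absent) > 0) {
    stop("data lacks column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(data)[vars]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  p_full <- length(block1) + length(block2)
  if (n <= p_full + 2) stop("too few complete rows (n = ", n, ")",
                            call. = FALSE)
  fml <- function(preds) {
    stats::as.formula(paste(outcome, "~",
                            paste(c("1", preds), collapse = " + ")))
  }
  fit1 <- stats::lm(fml(block1), data = df)
  fit_full <- stats::lm(fml(c(block1, block2)), data = df)
  if (any(is.na(stats::coef(fit_full)))) {
    stop("rank-deficient design: aliased predictor(s)", call. = FALSE)
  }
  r2_1 <- summary(fit1)$r.squared
  r2_f <- summary(fit_full)$r.squared

  block_fit <- function(fit, r2, p) {
    df2 <- n - p - 1
    f <- if (r2 >= 1) Inf else (r2 / p) / ((1 - r2) / df2)
    tibble::tibble(r.squared = r2, statistic = f, df1 = p, df2 = df2,
                   p.value = stats::pf(f, p, df2, lower.tail = FALSE))
  }
  blocks <- dplyr::bind_rows(
    dplyr::mutate(block_fit(fit1, r2_1, length(block1)), block = 1L),
    dplyr::mutate(block_fit(fit_full, r2_f, p_full), block = 2L)
  )[c("block", "r.squared", "statistic", "df1", "df2", "p.value")]
  q <- length(block2)
  delta_r2 <- r2_f - r2_1
  if (q > 0) {
    df2 <- n - p_full - 1
    delta_f <- if (r2_f >= 1) Inf else (delta_r2 / q) / ((1 - r2_f) / df2)
    blocks$delta_r2 <- c(NA_real_, delta_r2)
    blocks$delta_f <- c(NA_real_, delta_f)
    blocks$delta_p <- c(NA_real_,
                        stats::pf(delta_f, q, df2, lower.tail = FALSE))
  }

  coef_table <- function(fit, model, semipartials = NULL) {
    s <- summary(fit)$coefficients
    ci <- stats::confint(fit, level = conf_level)
    terms <- rownames(s)
    tibble::tibble(
      model = model,
      term = terms,
      estimate = unname(s[, 1]), se = unname(s[, 2]),
      conf.low = unname(ci[, 1]), conf.high = unname(ci[, 2]),
      statistic = unname(s[, 3]), p.value = unname(s[, 4]),
      semipartial = if (is.null(semipartials)) NA_real_ else
        unname(semipartials[terms])
    )
  }
  # semipartial r: signed sqrt of the unique R^2 contribution in the
  # full model when the predictor is removed alone
  preds <- c(block1, block2)
  sp <- vapply(preds, function(pr) {
    others <- setdiff(preds, pr)
    r2_wo <- if (length(others) == 0) 0 else
      summary(stats::lm(fml(others), data = df))$r.squared
    sqrt(max(0, r2_f - r2_wo)) * sign(stats::coef(fit_full)[[pr]])
  }, numeric(1))
  coefficients <- dplyr::bind_rows(
    coef_table(fit1, "initial"),
    coef_table(fit_full, "final", semipartials = sp)
  )
  structure(list(blocks = blocks, coefficients = coefficients, n = n,
                 outcome = outcome, block1 = block1, block2 = block2),
            class = "vad_hierreg")
}

#' @export
print.vad_hierreg <- function(x, ...) {
  cat("Hierarchical regression:", x$outcome, "~ [",
      paste(x$block1, collapse = ", "), "] + [",
      paste(x$block2, collapse = ", "), "], n =", x$n, "\n")
  print(x$blocks)
  print(x$coefficients, n = Inf)
  invisible(x)
}
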