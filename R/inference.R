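#' Bonferroni-adjusted significance level
#'
#' `alpha / k` at full precision. Decisions always compare at full
#' precision; [format_alpha()] reproduces the conventional truncated
#' display (e.g. `.05/3` shown as `".0166"`).
#'
#' @param alpha Family-wise level in (0, 1).
#' @param k Number of comparisons (>= 1).
#' @return `alpha / k`.
#' @examples
#' bonferroni_alpha(.05, 3)
#' format_alpha(bonferroni_alpha(.05, 3))  # ".0166"
#' @export
bonferroni_alpha <- function(alpha, k) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(k) || k < 1) stop("k must be >= 1", call. = FALSE)
  alpha / k
}

#' Truncated display of a significance level
#'
#' Truncates (does not round) to `digits` decimals and drops the leading
#' zero, matching the convention under which .05/3 is displayed ".0166".
#'
#' @param alpha Level in (0, 1).
#' @param digits Decimals kept (default 4).
#' @return Character scalar such as `".0166"`.
#' @export
format_alpha <- function(alpha, digits = 4) {
  truncated <- floor(alpha * 10^digits) / 10^digits
  sub("^0", "", sprintf(paste0("%.", digits, "f"), truncated))
}

#' Paired-samples t-test with d_z effect size
#'
#' Classic paired t on within-pair differences, dropping pairs with an
#' undefined value in either member. The effect size is the paired
#' Cohen's d_z = mean(diff) / sd(diff), whose sign follows
#' `mean(x) - mean(y)`; for non-degenerate data `d_z * sqrt(n) = t`
#' exactly. Zero-variance differences yield a degenerate result
#' (`degenerate = TRUE`, `t`/`p`/`d` undefined) rather than an error, so
#' pipelines over many outcomes stay total.
#'
#' @param x,y Numeric vectors of equal length (the two conditions).
#' @param conf_level Confidence level for the mean-difference CI
#'   (default 0.95).
#' @return An object of class `vad_paired_test`; see [tidy()] and
#'   [glance()] methods.
#' @examples
#' paired_t(c(5, 7, 6, 8), c(4, 6, 7, 5))
#' @export
paired_t <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) stop("need at least 2 complete pairs", call. = FALSE)
  d <- x - y
  sd_d <- stats::sd(d)
  out <- list(
    n_pairs = n,
    mean_x = mean(x), mean_y = mean(y),
    estimate = mean(d),
    se = sd_d / sqrt(n),
    df = n - 1,
    conf_level = conf_level,
    degenerate = sd_d == 0
  )
  if (out$degenerate) {
    out$statistic <- NA_real_
    out$p.value <- NA_real_
    out$cohen_d <- NA_real_
    out$conf.low <- out$estimate
    out$conf.high <- out$estimate
  } else {
    tt <- stats::t.test(x, y, paired = TRUE, conf.level = conf_level)
    out$statistic <- unname(tt$statistic)
    out$p.value <- tt$p.value
    out$cohen_d <- mean(d) / sd_d
    out$conf.low <- tt$conf.int[1]
    out$conf.high <- tt$conf.int[2]
  }
  structure(out, class = "vad_paired_test")
}

#' Independent-samples t-test with pooled-SD Cohen's d
#'
#' Welch's unequal-variance test by default (set `welch = FALSE` for the
#' Student pooled test). The effect size is the pooled-SD Cohen's d in
#' either case, with sign following `mean(x) - mean(y)`.
#'
#' @param x,y Numeric vectors (the two groups), each with >= 2
#'   non-missing values.
#' @param welch Use the Welch-Satterthwaite df (default `TRUE`).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `vad_independent_test`.
#' @export
independent_t <- function(x, y, welch = TRUE, conf_level = 0.95) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop("both groups are degenerate (zero variance)", call. = FALSE)
  }
  tt <- stats::t.test(x, y, var.equal = !welch, conf.level = conf_level)
  n1 <- length(x); n2 <- length(y)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
               (n1 + n2 - 2))
  structure(list(
    n_x = n1, n_y = n2,
    mean_x = mean(x), mean_y = mean(y),
    sd_x = stats::sd(x), sd_y = stats::sd(y),
    estimate = mean(x) - mean(y),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p.value = tt$p.value,
    conf.low = tt$conf.int[1], conf.high = tt$conf.int[2],
    conf_level = conf_level,
    cohen_d = (mean(x) - mean(y)) / sp,
    welch = welch
  ), class = "vad_independent_test")
}

#' Pearson correlation with two-tailed p
#'
#' Product-moment correlation via the t transform, dropping incomplete
#' pairs.
#'
#' @param x,y Numeric vectors; at least 3 complete pairs with non-zero
#'   variance.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `vad_cor`.
#' @export
pearson_r <- function(x, y, conf_level = 0.95) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("constant input: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, conf.level = conf_level)
  structure(list(
    n = length(x),
    estimate = unname(ct$estimate),
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p.value = ct$p.value,
    conf.low = ct$conf.int[1], conf.high = ct$conf.int[2],
    conf_level = conf_level
  ), class = "vad_cor")
}

#' Power of a two-tailed paired t-test
#'
#' Exact power from the noncentral t distribution: with `n` pairs,
#' df = n - 1 and noncentrality d * sqrt(n), the rejection probability at
#' two-tailed level `alpha`.
#'
#' @param n Number of pairs (>= 2); vectorised.
#' @param d Paired effect size d_z.
#' @param alpha Two-tailed significance level.
#' @return Numeric power in (0, 1).
#' @export
paired_power <- function(n, d, alpha) {
  vapply(n, function(ni) {
    df <- ni - 1
    tcrit <- stats::qt(1 - alpha / 2, df)
    ncp <- d * sqrt(ni)
    stats::pt(-tcrit, df, ncp = ncp) + 1 - stats::pt(tcrit, df, ncp = ncp)
  }, numeric(1))
}

#' Required sample size for a paired t-test
#'
#' Smallest n >= 2 whose two-tailed paired-t power (noncentral t,
#' df = n - 1, noncentrality d * sqrt(n)) reaches the target, found by
#' upward iteration; also returns the achieved power. Power is strictly
#' increasing in n for fixed d != 0, so the first hit is the minimum.
#'
#' @param d Paired effect size d_z (non-zero).
#' @param alpha Two-tailed significance level.
#' @param power Target power in (0, 1).
#' @param n_max Safety cap on the search (default 1e6).
#' @return An object of class `vad_power` with fields `n`,
#'   `achieved_power`, `d`, `alpha`, `power`.
#' @examples
#' required_n_paired(d = 0.15, alpha = 0.0166, power = 0.95)$n  # 729
#' @export
required_n_paired <- function(d, alpha, power, n_max = 1e6) {
  if (d == 0) stop("power unreachable at d = 0", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)",
                                     call. = FALSE)
  if (power <= 0 || power >= 1) stop("power must lie in (0, 1)",
                                     call. = FALSE)
  d <- abs(d)
  # bracket with a geometric scan, then resolve exactly by iteration
  n <- 2
  while (n < n_max && paired_power(n, d, alpha) < power) n <- n * 2
  lo <- max(2, n %/% 2)
  n <- lo
  while (n <= n_max && paired_power(n, d, alpha) < power) n <- n + 1
  if (n > n_max) stop("no n <= n_max reaches the target power",
                      call. = FALSE)
  structure(list(
    n = as.integer(n),
    achieved_power = paired_power(n, d, alpha),
    d = d, alpha = alpha, power = power
  ), class = "vad_power")
}

#' Skewness and excess kurtosis of score variables
#'
#' Descriptive moments (mean, sd, skewness, excess kurtosis) for selected
#' columns -- the package's normality diagnostics are descriptive only.
#'
#' @param data A data frame.
#' @param cols Columns to summarise (default: the nine score variables
#'   present in `data`).
#' @return A tibble with one row per column.
#' @export
score_moments <- function(data, cols = intersect(analysis_score_columns(),
                                                 names(data))) {
  purrr::map_dfr(cols, function(col) {
    x <- data[[col]]
    x <- x[!is.na(x)]
    n <- length(x)
    m <- mean(x); s <- stats::sd(x)
    tibble::tibble(
      variable = col, n = n, mean = m, sd = s,
      skewness = if (n > 2 && s > 0) sum((x - m)^3) / n / s^3 else NA_real_,
      kurtosis_excess = if (n > 3 && s > 0) {
        sum((x - m)^4) / n / s^4 - 3
      } else NA_real_
    )
  })
}

#' @export
print.vad_paired_test <- function(x, ...) {
  cat("Paired t-test: n =", x$n_pairs, "pairs\n")
  cat(sprintf("  mean diff %.4f (SE %.4f), %g%% CI [%.4f, %.4f]\n",
              x$estimate, x$se, 100 * x$conf_level, x$conf.low, x$conf.high))
  if (x$degenerate) {
    cat("  degenerate: zero-variance differences; t, p, d undefined\n")
  } else {
    cat(sprintf("  t(%d) = %.3f, p = %.4g, d_z = %.3f\n",
                x$df, x$statistic, x$p.value, x$cohen_d))
  }
  invisible(x)
}

#' @export
print.vad_independent_test <- function(x, ...) {
  cat(sprintf("Independent t-test (%s): n = %d vs %d\n",
              if (x$welch) "Welch" else "Student", x$n_x, x$n_y))
  cat(sprintf("  mean diff %.4f, t(%.2f) = %.3f, p = %.4g, d = %.3f\n",
              x$estimate, x$df, x$statistic, x$p.value, x$cohen_d))
  invisible(x)
}

#' @export
print.vad_cor <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d), t(%d) = %.3f, p = %.4g\n",
              x$estimate, x$n, x$df, x$statistic, x$p.value))
  invisible(x)
}

#' @export
print.vad_power <- function(x, ...) {
  cat(sprintf(
    "Paired-t power analysis: d = %.3f, alpha = %s (two-tailed), target %.2f\n",
    x$d, format_alpha(x$alpha), x$power))
  cat(sprintf("  required n = %d (achieved power %.4f)\n",
              x$n, x$achieved_power))
  invisible(x)
}
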