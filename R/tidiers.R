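#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a paired t-test
#' @param x A `vad_paired_test`.
#' @param ... Unused.
#' @return One-row tibble with estimate, CI, statistic, df, p, d_z.
#' @export
tidy.vad_paired_test <- function(x, ...) {
  tibble::tibble(
    estimate = x$estimate, se = x$se,
    conf.low = x$conf.low, conf.high = x$conf.high,
    statistic = x$statistic, df = x$df, p.value = x$p.value,
    cohen_d = x$cohen_d, n_pairs = x$n_pairs,
    mean_a = x$mean_x, mean_b = x$mean_y,
    degenerate = x$degenerate
  )
}

#' @rdname tidy.vad_paired_test
#' @export
glance.vad_paired_test <- function(x, ...) tidy(x, ...)

#' Tidy an independent t-test
#' @param x A `vad_independent_test`.
#' @param ... Unused.
#' @export
tidy.vad_independent_test <- function(x, ...) {
  tibble::tibble(
    estimate = x$estimate, statistic = x$statistic, df = x$df,
    p.value = x$p.value, conf.low = x$conf.low, conf.high = x$conf.high,
    cohen_d = x$cohen_d, n_x = x$n_x, n_y = x$n_y,
    mean_x = x$mean_x, mean_y = x$mean_y, sd_x = x$sd_x, sd_y = x$sd_y
  )
}

#' Tidy a correlation result
#' @param x A `vad_cor`.
#' @param ... Unused.
#' @export
tidy.vad_cor <- function(x, ...) {
  tibble::tibble(
    estimate = x$estimate, statistic = x$statistic, df = x$df,
    p.value = x$p.value, conf.low = x$conf.low, conf.high = x$conf.high,
    n = x$n
  )
}

#' Tidy a pooled estimate
#' @param x A `vad_pooled`.
#' @param ... Unused.
#' @export
tidy.vad_pooled <- function(x, ...) {
  tibble::tibble(
    estimate = x$estimate, se = x$se, statistic = x$statistic,
    df = x$df, p.value = x$p.value,
    conf.low = x$conf.low, conf.high = x$conf.high,
    W = x$W, B = x$B, T = x$T, fmi = x$fmi, m = x$m
  )
}

#' Tidy a power analysis
#' @param x A `vad_power`.
#' @param ... Unused.
#' @export
tidy.vad_power <- function(x, ...) {
  tibble::tibble(n = x$n, achieved_power = x$achieved_power,
                 d = x$d, alpha = x$alpha, target_power = x$power)
}

#' Tidy a hierarchical regression (coefficients)
#' @param x A `vad_hierreg`.
#' @param ... Unused.
#' @export
tidy.vad_hierreg <- function(x, ...) x$coefficients

#' Per-block fit of a hierarchical regression
#' @param x A `vad_hierreg`.
#' @param ... Unused.
#' @export
glance.vad_hierreg <- function(x, ...) x$blocks
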