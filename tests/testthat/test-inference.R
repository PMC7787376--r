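test_that("bonferroni level is exact with truncated display", {
  a3 <- bonferroni_alpha(.05, 3)
  expect_equal(a3, 0.05 / 3)
  expect_equal(format_alpha(a3), ".0166")  # truncated, not rounded
  expect_equal(bonferroni_alpha(.05, 1), .05)
  expect_equal(bonferroni_alpha(.05, 5), .01)
  expect_error(bonferroni_alpha(.05, 0), ">= 1")
  expect_error(bonferroni_alpha(1.5, 3), "alpha")
})

test_that("paired_t matches the hand formula oracle exactly", {
  x <- c(5, 7, 6, 8); y <- c(4, 6, 7, 5)
  got <- paired_t(x, y)
  want <- oracle_paired_t(x, y)
  expect_equal(got$estimate, want$mean_diff, tolerance = 1e-10)
  expect_equal(got$statistic, want$t, tolerance = 1e-10)
  expect_equal(got$p.value, want$p, tolerance = 1e-10)
  expect_equal(got$cohen_d, want$d_z, tolerance = 1e-10)
  expect_equal(got$df, 3)
})

test_that("degenerate paired differences are flagged, not fatal", {
  same <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_true(same$degenerate)
  expect_equal(same$estimate, 0)
  expect_true(is.na(same$cohen_d))

  shift <- paired_t(c(1, 2, 3), c(0, 1, 2))
  expect_true(shift$degenerate)
  expect_equal(shift$estimate, 1)

  expect_error(paired_t(1, 1), "at least 2")
  expect_error(paired_t(1:3, 1:2), "equal length")
})

test_that("incomplete pairs are dropped before testing", {
  x <- c(5, 7, NA, 8, 6); y <- c(4, NA, 6, 5, 7)
  got <- paired_t(x, y)
  expect_equal(got$n_pairs, 3)
  expect_equal(got$estimate, mean(c(5 - 4, 8 - 5, 6 - 7)))
})

test_that("d_z * sqrt(n) equals t across random paired fixtures", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- paired_t(x, y)
    expect_equal(got$cohen_d * sqrt(n), got$statistic, tolerance = 1e-9)
  }
})

test_that("independent_t reproduces the Welch oracle and conventions", {
  x <- c(4.1, 5.2, 6.0, 5.5); y <- c(3.0, 4.8, 3.9, 2.2)
  got <- independent_t(x, y)
  want <- oracle_welch_t(x, y)
  expect_equal(got$statistic, want$t, tolerance = 1e-10)
  expect_equal(got$df, want$df, tolerance = 1e-10)
  expect_equal(got$p.value, want$p, tolerance = 1e-10)
  # pooled-SD d
  sp <- sqrt((3 * var(x) + 3 * var(y)) / 6)
  expect_equal(got$cohen_d, (mean(x) - mean(y)) / sp, tolerance = 1e-10)
  expect_equal(sign(got$cohen_d), sign(got$estimate))

  # identical groups: t = 0
  z <- c(1, 2, 3, 4)
  expect_equal(independent_t(z, z)$statistic, 0)
  # equal variance, equal n: Welch df equals Student df
  set.seed(2)
  a <- rnorm(10); b <- a + 0.3  # same spread
  expect_equal(independent_t(a, b, welch = TRUE)$df, 18)
  expect_error(independent_t(c(1, 1), c(2, 2)), "degenerate")
})

test_that("pearson_r handles exact and hand-worked cases", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, x)$estimate, 1)
  expect_equal(pearson_r(x, -x)$estimate, -1)
  y <- c(2.0, 2.9, 4.2, 3.8, 5.4)
  got <- pearson_r(x, y)
  r <- sum((x - 3) * (y - mean(y))) /
    sqrt(sum((x - 3)^2) * sum((y - mean(y))^2))
  t <- r * sqrt(3 / (1 - r^2))
  expect_equal(got$estimate, r, tolerance = 1e-10)
  expect_equal(got$statistic, t, tolerance = 1e-10)
  expect_equal(got$p.value, 2 * pt(-abs(t), 3), tolerance = 1e-10)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("required_n_paired is minimal and correct at the study settings", {
  res <- required_n_paired(d = 0.15, alpha = 0.0166, power = 0.95)
  expect_equal(res$n, 729L)
  expect_gte(res$achieved_power, 0.95)
  # minimality: one fewer pair is underpowered
  expect_lt(paired_power(res$n - 1, 0.15, 0.0166), 0.95)
  expect_error(required_n_paired(0, .05, .8), "d = 0")
})

test_that("required n is monotone in effect size, power and alpha", {
  base <- required_n_paired(.3, .05, .8)$n
  expect_lte(required_n_paired(.5, .05, .8)$n, base)     # larger d
  expect_gte(required_n_paired(.3, .05, .95)$n, base)    # more power
  expect_gte(required_n_paired(.3, .01, .8)$n, base)     # stricter alpha
  expect_equal(required_n_paired(-.3, .05, .8)$n, base)  # sign-free
})

test_that("large-n requirements agree with the normal approximation", {
  for (d in c(.1, .15, .2)) {
    got <- required_n_paired(d, .05, .9)$n
    # second-order normal approximation for a one-sample/paired t
    approx <- ((qnorm(.975) + qnorm(.9)) / d)^2 + qnorm(.975)^2 / 2
    expect_gte(got, 100)
    expect_lte(abs(got - approx), 2)
  }
})

test_that("noncentral-t power agrees with simulation at a textbook setting", {
  res <- required_n_paired(d = 0.8, alpha = 0.05, power = 0.8)
  set.seed(99)
  reps <- 4000
  diffs <- matrix(rnorm(reps * res$n, mean = 0.8, sd = 1), nrow = res$n)
  tstat <- colMeans(diffs) / (apply(diffs, 2, sd) / sqrt(res$n))
  reject <- mean(abs(tstat) > qt(0.975, res$n - 1))
  expect_lt(abs(reject - res$achieved_power), 0.02)
})

test_that("hierarchical regression reports blocks, increments, semipartials", {
  set.seed(5)
  n <- 300
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  y <- 0.5 * x1 + 0.3 * x2 - 0.2 * x3 + rnorm(n)
  df <- tibble::tibble(y = y, x1 = x1, x2 = x2, x3 = x3)
  fit <- hier_regression(df, "y", "x1", c("x2", "x3"))
  expect_equal(nrow(fit$blocks), 2)
  expect_gte(fit$blocks$delta_r2[2], 0)
  expect_true(all(fit$blocks$p.value >= 0 & fit$blocks$p.value <= 1))
  # semipartial^2 of a predictor never exceeds the block increment it joined in
  final <- fit$coefficients[fit$coefficients$model == "final", ]
  expect_lte(final$semipartial[final$term == "x2"]^2,
             fit$blocks$delta_r2[2] + 1e-12)
  # coefficient table matches lm directly
  lmfit <- lm(y ~ x1 + x2 + x3, data = df)
  expect_equal(final$estimate[-1], unname(coef(lmfit))[-1],
               tolerance = 1e-10)
})

test_that("orthogonal standardised predictors give additive R-squared", {
  # build exactly orthogonal unit-variance predictors
  set.seed(8)
  n <- 64
  raw <- matrix(rnorm(n * 3), ncol = 3)
  q <- qr.Q(qr(cbind(1, raw)))[, 2:4] * sqrt(n - 1)
  y <- q %*% c(.4, .3, .2) + rnorm(n)
  df <- tibble::tibble(y = as.vector(y), a = q[, 1], b = q[, 2], c = q[, 3])
  fit <- hier_regression(df, "y", "a", c("b", "c"))
  r2_sum <- cor(df$y, df$b)^2 + cor(df$y, df$c)^2
  expect_equal(fit$blocks$delta_r2[2], r2_sum, tolerance = 1e-10)
})

test_that("regression is invariant to predictor order within a block", {
  set.seed(13)
  df <- tibble::tibble(y = rnorm(50), a = rnorm(50), b = rnorm(50),
                       c = rnorm(50))
  f1 <- hier_regression(df, "y", "a", c("b", "c"))
  f2 <- hier_regression(df, "y", "a", c("c", "b"))
  expect_equal(f1$blocks$r.squared, f2$blocks$r.squared)
  expect_equal(f1$blocks$delta_r2, f2$blocks$delta_r2)
})

test_that("regression degenerate cases error clearly", {
  df <- tibble::tibble(y = rnorm(30), a = rnorm(30))
  df$b <- df$a  # aliased
  expect_error(hier_regression(df, "y", "a", "b"), "rank-deficient")
  expect_error(hier_regression(df[1:3, ], "y", "a"), "too few")
  expect_error(hier_regression(df, "z", "a"), "lacks column")
  # a perfect copy of the outcome as block-1 predictor: perfect fit
  df$ycopy <- df$y
  fit <- suppressWarnings(hier_regression(df, "y", "ycopy"))
  expect_equal(fit$blocks$r.squared[1], 1, tolerance = 1e-12)
})

test_that("score_moments reports n-weighted skew and excess kurtosis", {
  x <- c(1, 2, 3, 4, 50)
  m <- score_moments(tibble::tibble(v = x), cols = "v")
  z <- (x - mean(x)) / sd(x)
  expect_equal(m$skewness, mean(z^3))
  expect_equal(m$kurtosis_excess, mean(z^4) - 3)
})
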